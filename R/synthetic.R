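# Synthetic sequence families with controlled within-family similarity.
#
# Each family descends from a single ancestor (a tiled motif, a
# composition-weighted random draw, or both) by independent per-site
# substitution with probability mu, uniform over the three alternative
# bases.  No indels: family members share their ancestor's length, so
# cross-family length differences are the only source of padding.

BASES <- c("A", "C", "G", "T")

#' Specification of one synthetic sequence family
#'
#' @param family Family id (used as group label and id prefix).
#' @param n Number of sequences to draw.
#' @param length Sequence length (>= motif length when a motif is given).
#' @param mu Per-site substitution probability in \[0, 1\] applied
#'   independently to every descendant site (uniform over the 3 other
#'   bases).
#' @param motif Optional motif string tiled to build the ancestor (e.g.
#'   `"AT"` gives a period-2 ancestor `ATATAT...`).
#' @param composition Ancestor base weights over A, C, G, T (must sum to
#'   1); used when no motif is given.
#' @return A validated `family_spec` list.
#' @export
family_spec <- function(family, n, length, mu,
                        motif = NULL,
                        composition = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25)) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu > 1) {
    stop("mu must be a single value in [0, 1], got ", mu, call. = FALSE)
  }
  n <- as.integer(n)
  length <- as.integer(length)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (!is.null(motif)) {
    motif <- gsub("U", "T", toupper(motif), fixed = TRUE)
    if (!grepl("^[ACGT]+$", motif)) {
      stop("motif must be a non-empty string over A, C, G, T", call. = FALSE)
    }
    if (nchar(motif) > length) {
      stop("length (", length, ") is shorter than the motif (",
           nchar(motif), ")", call. = FALSE)
    }
  }
  composition <- as.numeric(composition)
  if (length(composition) != 4L || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9) {
    stop("composition must be 4 nonnegative weights over A, C, G, T summing",
         " to 1", call. = FALSE)
  }
  structure(list(family = as.character(family), n = n, length = length,
                 mu = mu, motif = motif, composition = composition),
            class = "family_spec")
}

.draw_ancestor <- function(spec) {
  if (!is.null(spec$motif)) {
    tiles <- strsplit(spec$motif, "", fixed = TRUE)[[1]]
    rep_len(tiles, spec$length)
  } else {
    sample(BASES, spec$length, replace = TRUE, prob = spec$composition)
  }
}

#' Generate one synthetic family
#'
#' Draws the family's ancestor, then `n` descendants by independent
#' per-site substitution with probability `mu`.  Ids are
#' `<family>_<replicate>`.  Uses the caller's RNG state unless `seed` is
#' given.
#'
#' @param spec A [family_spec()].
#' @param seed Optional integer seed.
#' @return A `dna_set` with an `ancestor` attribute (the ancestor string).
#' @export
generate_family <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ancestor <- .draw_ancestor(spec)
  L <- spec$length
  seqs <- character(spec$n)
  for (i in seq_len(spec$n)) {
    child <- ancestor
    hit <- stats::runif(L) < spec$mu
    if (any(hit)) {
      # uniform over the 3 alternative bases at each substituted site
      for (pos in which(hit)) {
        child[pos] <- sample(setdiff(BASES, child[pos]), 1L)
      }
    }
    seqs[[i]] <- paste(child, collapse = "")
  }
  out <- dna_set(id = sprintf("%s_%02d", spec$family, seq_len(spec$n)),
                 residues = seqs,
                 description = paste("synthetic family", spec$family))
  attr(out, "ancestor") <- paste(ancestor, collapse = "")
  out
}

#' Generate a labeled multi-family synthetic dataset
#'
#' Concatenates the families drawn from `specs`, shuffles the sequence
#' order, and returns both the sequences and a `group_table` with the
#' planted family as the single group level.
#'
#' @param specs List of [family_spec()] objects with distinct family ids.
#' @param seed Master integer seed; the same seed reproduces the dataset
#'   byte for byte.
#' @return List with `sequences` (a `dna_set`) and `groups` (a
#'   `group_table` with level `family`).
#' @export
generate_dataset <- function(specs, seed = 1L) {
  if (length(specs) < 1L) stop("need at least one family spec", call. = FALSE)
  fams <- vapply(specs, function(s) s$family, character(1))
  if (anyDuplicated(fams)) {
    stop("duplicate family id(s): ",
         paste(unique(fams[duplicated(fams)]), collapse = ", "),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  parts <- lapply(specs, generate_family)
  seqs <- do.call(rbind, lapply(parts, as.data.frame))
  labels <- rep(fams, vapply(specs, function(s) s$n, integer(1)))
  ord <- sample.int(nrow(seqs))
  seqs <- seqs[ord, , drop = FALSE]
  labels <- labels[ord]
  rownames(seqs) <- NULL
  class(seqs) <- c("dna_set", "data.frame")
  groups <- group_table(data.frame(id = seqs$id, family = labels,
                                   stringsAsFactors = FALSE))
  list(sequences = seqs, groups = groups)
}

#' Read a family-spec table for simulation
#'
#' Parses a CSV/TSV with header columns `family,n,length,mu` and optional
#' `motif,comp_a,comp_c,comp_g,comp_t` into a list of [family_spec()]s.
#' An empty `motif` cell means composition sampling.
#'
#' @param path Path to the spec table.
#' @return List of `family_spec` objects.
#' @export
read_family_specs <- function(path) {
  if (!file.exists(path)) {
    stop("spec file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", fill = FALSE)
  required <- c("family", "n", "length", "mu")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("spec file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    motif <- if ("motif" %in% names(tab) && nzchar(trimws(row$motif))) {
      trimws(row$motif)
    } else NULL
    comp <- if (all(c("comp_a", "comp_c", "comp_g", "comp_t") %in%
                      names(tab))) {
      as.numeric(row[c("comp_a", "comp_c", "comp_g", "comp_t")])
    } else c(0.25, 0.25, 0.25, 0.25)
    family_spec(family = row$family, n = as.numeric(row$n),
                length = as.numeric(row$length), mu = as.numeric(row$mu),
                motif = motif, composition = comp)
  })
}
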