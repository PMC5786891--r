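# Sequence and metadata I/O: FASTA in, tabular assignments/coordinates out.

# IUPAC nucleotide codes accepted at parse time.  'U' is normalized to 'T'
# on read; everything outside this set is rejected with a position.
IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Read nucleotide sequences from a FASTA file
#'
#' Parses a multi-FASTA file into a `dna_set`: a data frame with one row per
#' record and columns `id` (first whitespace-delimited header token),
#' `description` (remainder of the header) and `residues` (uppercased
#' sequence).  IUPAC ambiguity codes are accepted; `U` is converted to `T`.
#' Record order is preserved exactly.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped sequence lines).
#' @return A data frame of class `dna_set` with columns `id`, `description`,
#'   `residues`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 example", "ATTCGCAT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no sequences found in ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    stop("empty sequence id in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  residues <- toupper(as.character(set))
  residues <- gsub("U", "T", residues, fixed = TRUE)
  for (i in seq_along(residues)) {
    if (nchar(residues[[i]]) == 0L) {
      stop("sequence '", ids[[i]], "' is empty", call. = FALSE)
    }
    bad <- which(!(strsplit(residues[[i]], "", fixed = TRUE)[[1]] %in%
                     IUPAC_CODES))
    if (length(bad) > 0L) {
      stop("illegal character in sequence '", ids[[i]], "' at position ",
           bad[[1]], call. = FALSE)
    }
  }
  dna_set(ids, residues, desc)
}

#' Construct a `dna_set` from vectors of ids and residues
#'
#' @param id Character vector of unique, non-empty sequence ids.
#' @param residues Character vector of IUPAC nucleotide strings (uppercased
#'   internally; `U` mapped to `T`).
#' @param description Optional character vector of free-text descriptions.
#' @return A data frame of class `dna_set`.
#' @export
dna_set <- function(id, residues, description = "") {
  stopifnot(length(id) == length(residues))
  if (any(id == "") || anyDuplicated(id)) {
    stop("sequence ids must be non-empty and unique", call. = FALSE)
  }
  residues <- gsub("U", "T", toupper(residues), fixed = TRUE)
  if (any(nchar(residues) == 0L)) {
    stop("sequences must have length >= 1", call. = FALSE)
  }
  out <- data.frame(id = as.character(id),
                    description = rep_len(as.character(description),
                                          length(id)),
                    residues = residues,
                    stringsAsFactors = FALSE)
  class(out) <- c("dna_set", "data.frame")
  out
}

#' Write a `dna_set` to a FASTA file
#'
#' @param seqs A `dna_set`.
#' @param path Output path.
#' @param width Line-wrap width for residues (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    header <- if (nzchar(seqs$description[[i]])) {
      paste(seqs$id[[i]], seqs$description[[i]])
    } else {
      seqs$id[[i]]
    }
    writeLines(paste0(">", header), con)
    s <- seqs$residues[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a sequence-to-group metadata table
#'
#' Reads a tab- or comma-separated file whose first column (named `id`,
#' case-insensitively) holds sequence ids and whose remaining columns are
#' ordered grouping levels (e.g. kingdom, phylum, class).  Missing or empty
#' labels are stored as the explicit label `"Unknown"`.
#'
#' @param path Path to the delimited file (separator auto-detected from the
#'   header line).
#' @return A data frame of class `group_table`; attribute `levels` holds the
#'   ordered grouping level names.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) {
    stop("groups file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = FALSE)
  if (ncol(tab) < 1L || tolower(names(tab)[[1]]) != "id") {
    stop("groups file must have an 'id' first column", call. = FALSE)
  }
  names(tab)[[1]] <- "id"
  if (ncol(tab) < 2L) {
    stop("groups file has no group-level columns", call. = FALSE)
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate id(s) in groups file: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (j in 2:ncol(tab)) {
    blank <- is.na(tab[[j]]) | !nzchar(trimws(tab[[j]]))
    tab[[j]][blank] <- "Unknown"
  }
  group_table(tab)
}

#' Construct a `group_table` from a data frame
#'
#' @param df Data frame with an `id` column followed by one or more ordered
#'   group-level columns.
#' @return The data frame with class `group_table` and a `levels` attribute.
#' @export
group_table <- function(df) {
  stopifnot(is.data.frame(df), "id" %in% names(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  lev <- setdiff(names(df), "id")
  if (length(lev) == 0L) stop("group table needs at least one group level")
  attr(df, "levels") <- lev
  class(df) <- c("group_table", "data.frame")
  df
}

#' Group labels for a set of ids at one level
#'
#' @param groups A `group_table`.
#' @param ids Character vector of sequence ids.
#' @param level Group level name (default: first level).
#' @return Character vector of labels aligned with `ids`; ids absent from the
#'   table get `"Unknown"` with a warning.
#' @export
group_labels <- function(groups, ids, level = NULL) {
  lev <- attr(groups, "levels")
  if (is.null(level)) level <- lev[[1]]
  if (!level %in% lev) {
    stop("unknown group level '", level, "'; available: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  idx <- match(ids, groups$id)
  if (anyNA(idx)) {
    warning("ids missing from group table: ",
            paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- rep("Unknown", length(ids))
  out[!is.na(idx)] <- groups[[level]][idx[!is.na(idx)]]
  out
}

#' Write cluster assignments as TSV
#'
#' Writes one row per sequence with columns `id`, `cluster` (1-based labels
#' `C-1`, `C-2`, ... as used in the plots) and `distance_to_centroid`
#' (Euclidean distance of the sequence's spectrum to its cluster centroid).
#' Row order equals input order.
#'
#' @param model A `cluster_model` from [kmeans_fit()].
#' @param ids Character vector of sequence ids, same length and order as the
#'   model's label vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(model, ids, path) {
  if (length(ids) != length(model$labels)) {
    stop("ids (", length(ids), ") and model labels (", length(model$labels),
         ") differ in length", call. = FALSE)
  }
  df <- data.frame(id = ids,
                   cluster = paste0("C-", model$labels),
                   distance_to_centroid = model$distances,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster-assignments TSV back into a label vector
#'
#' Inverse of [write_assignments()]: returns the integer label vector (named
#' by sequence id) encoded in the `cluster` column.
#'
#' @param path Path to an assignments TSV.
#' @return Named integer vector of 1-based cluster labels.
#' @export
read_assignments <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  labels <- as.integer(sub("^C-", "", df$cluster))
  names(labels) <- df$id
  labels
}
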