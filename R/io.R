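# Readers/writers for the delimited-table and tree formats the pipeline
# consumes. All tables are plain text, comma- or tab-separated; the
# delimiter is sniffed from the header line. Trees and dendrograms are
# newick (ape).

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) return(",")
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab > n_com) "\t" else ","
}

read_table_auto <- function(path) {
  utils::read.table(path, header = TRUE, sep = sniff_delim(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}

#' Read an FTICR-MS peak table
#'
#' Reads a delimited text table of assigned molecular-formula peaks:
#' one row per (sample, peak), with columns \code{sample_id}, \code{mz}
#' and element counts \code{C,H,O,N,S,P} (S and P optional, default 0),
#' plus an optional \code{intensity}. Formula assignment happens
#' upstream; this reader only validates what it is given.
#'
#' Each row's m/z is checked against the monoisotopic mass computed
#' from its formula; rows deviating by more than \code{tolerance} are
#' flagged in the \code{mass_flag} column, never dropped (set
#' \code{drop_flagged = TRUE} to discard them). The number of flagged
#' rows is reported via \code{message()}.
#'
#' @param path delimited text file with a header.
#' @param tolerance mass-consistency tolerance in Da (default 0.005).
#' @param drop_flagged discard mass-inconsistent rows instead of
#'   flagging them.
#' @return data frame of class \code{peak_table} with columns
#'   sample_id, mz, C, H, O, N, S, P, intensity (NA if absent),
#'   mass_flag.
#' @export
read_peak_table <- function(path, tolerance = 0.005, drop_flagged = FALSE) {
  tb <- read_table_auto(path)
  required <- c("sample_id", "mz", "C", "H", "O")
  miss <- setdiff(required, names(tb))
  if (length(miss)) {
    stop("peak table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (el in c("N", "S", "P")) {
    if (is.null(tb[[el]])) tb[[el]] <- rep(0L, nrow(tb))
  }
  if (is.null(tb$intensity)) tb$intensity <- rep(NA_real_, nrow(tb))
  if (nrow(tb) == 0) {
    tb$mass_flag <- logical(0)
    class(tb) <- c("peak_table", class(tb))
    return(tb)
  }
  if (any(is.na(tb$sample_id)) || any(tb$sample_id == "")) {
    stop("every peak row must carry a sample_id")
  }
  for (el in ELEMENTS) {
    v <- tb[[el]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v)) || any(v < 0)) {
      stop("non-integer or negative element count in column ", el)
    }
    tb[[el]] <- as.integer(v)
  }
  allzero <- rowSums(as.matrix(tb[ELEMENTS])) == 0
  if (any(allzero)) stop("rows with all-zero element counts: ",
                         paste(which(allzero), collapse = ", "))
  if (any(tb$mz <= 0)) stop("mz must be positive")
  tb$mass_flag <- abs(formula_mass(tb) - tb$mz) > tolerance
  nflag <- sum(tb$mass_flag)
  if (nflag > 0) {
    message(nflag, " peak(s) flagged mass-inconsistent (tolerance ",
            tolerance, " Da)")
  }
  if (drop_flagged) tb <- tb[!tb$mass_flag, , drop = FALSE]
  class(tb) <- c("peak_table", class(tb))
  tb
}

#' Read sample metadata
#'
#' Reads the sample table mapping opaque sample ids to the crossed
#' design factors: \code{treatment} (e.g. P1/P5/P10 mono-cropping
#' durations), \code{stage} (e.g. W6/W10 growth stages) and
#' \code{replicate}. (treatment, stage, replicate) must be unique.
#'
#' @param path delimited text file with header columns sample_id,
#'   treatment, stage, replicate.
#' @return data frame with factor columns treatment and stage.
#' @export
read_sample_metadata <- function(path) {
  tb <- read_table_auto(path)
  need <- c("sample_id", "treatment", "stage", "replicate")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tb$sample_id)) stop("duplicate sample_id in metadata")
  key <- paste(tb$treatment, tb$stage, tb$replicate)
  if (anyDuplicated(key)) {
    stop("(treatment, stage, replicate) combinations must be unique")
  }
  tb$treatment <- factor(tb$treatment)
  tb$stage <- factor(tb$stage)
  tb
}

#' Read a community count matrix and its phylogeny
#'
#' Reads a features-by-samples count table (first column = feature id)
#' together with a newick tree whose tips supply patristic distances.
#' Features absent from the tree are dropped with a warning; zero
#' overlap or a tree without branch lengths is an error.
#'
#' @param path_counts delimited text count table, first column feature
#'   ids, remaining columns one per sample.
#' @param path_tree newick file with branch lengths.
#' @return list with \code{counts} (matrix, features x samples) and
#'   \code{tree} (ape \code{phylo}).
#' @export
read_community <- function(path_counts, path_tree) {
  tb <- read_table_auto(path_counts)
  ids <- as.character(tb[[1]])
  counts <- as.matrix(tb[, -1, drop = FALSE])
  rownames(counts) <- ids
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  tree <- ape::read.tree(path_tree)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; patristic distances are undefined")
  }
  keep <- ids %in% tree$tip.label
  if (!any(keep)) stop("no overlap between count features and tree tips")
  if (any(!keep)) {
    warning(sum(!keep), " feature(s) absent from the tree were dropped")
    counts <- counts[keep, , drop = FALSE]
  }
  list(counts = counts, tree = tree)
}

#' Write / read a labelled square distance matrix
#'
#' Distance matrices are stored as square delimited tables with row and
#' column sample labels; optional header comment lines (\code{#}) carry
#' provenance such as the permutation count and seed.
#'
#' @param d \code{dist} object or square matrix.
#' @param path output file.
#' @param comments character vector written as \code{# ...} lines.
#' @export
write_distance_matrix <- function(d, path, comments = character()) {
  m <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c("sample", colnames(m)), collapse = ","), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i],
                       format(m[i, ], digits = 17, trim = TRUE,
                              scientific = FALSE)),
                     collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @return \code{read_distance_matrix}: a labelled square matrix.
#' @export
read_distance_matrix <- function(path) {
  tb <- read_table_auto(path)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- as.character(tb[[1]])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("not a labelled square matrix: ", path)
  }
  m
}

write_table_commented <- function(tb, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(tb, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
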