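# Readers/writers for the flat formats the pipeline touches. Dialect is
# strict: tab-delimited, UTF-8, no quoting; malformed input is rejected,
# never coerced.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' every cell must parse as a finite number. Duplicated ids and
#' non-numeric cells are rejected with the offending row/column named.
#'
#' @param path Path to a tab-delimited file.
#' @param role Role tag (`"mRNA"`, `"lncRNA"`, `"miRNA"`).
#' @param unit Unit tag (`"counts"`, `"CPM"`, `"FPKM"`, `"log2CPM"`,
#'   `"log2FPKM"`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, role, unit) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2) stop("malformed header in ", path,
                         ": need a gene-id column plus >= 1 sample column")
  gid <- df[[1]]
  if (anyDuplicated(gid))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  sid <- colnames(df)[-1]
  vals <- matrix(NA_real_, nrow(df), length(sid),
                 dimnames = list(gid, sid))
  for (j in seq_along(sid)) {
    x <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(!is.finite(x))
    if (length(bad))
      stop("non-numeric cell at gene '", gid[bad[1]], "', sample '",
           sid[j], "' (value '", df[[j + 1]][bad[1]], "')")
    vals[, j] <- x
  }
  expression_matrix(vals, role = role, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass_mat(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical sample table from TSV
#'
#' Required columns: `sample_id`, `patient_id`, `condition`
#' (tumor/normal). Optional: `pair_id`, `tnm_stage` (I-IV),
#' `survival_time` (days), `event` (0 censored / 1 death). Empty strings
#' and `NA` denote missing optional values. The tumor/normal pairing
#' invariant is enforced.
#'
#' @param path Path to a tab-delimited file.
#' @return A [clinical_table()].
#' @export
read_clinical_table <- function(path) {
  df <- read_tsv_strict(path)
  for (cc in intersect(c("pair_id", "tnm_stage"), names(df)))
    df[[cc]][!nzchar(df[[cc]])] <- NA
  for (cc in intersect(c("survival_time", "event"), names(df))) {
    v <- df[[cc]]
    v[!nzchar(v) | v == "NA"] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num)))
      stop("non-numeric ", cc, " in ", path)
    df[[cc]] <- num
  }
  clinical_table(df)
}

#' Write a clinical table to TSV
#' @param x A [clinical_table()].
#' @param path Output path.
#' @export
write_clinical_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a two-column miRNA-to-target edge table
#'
#' File rows are `(mirna_id, target_id)`; a header row named exactly
#' `mirna_id<TAB>target_id` is accepted and skipped. Duplicates are
#' dropped with a message reporting the count; an empty file yields an
#' empty table with a warning.
#'
#' @param path Path to a tab-delimited two-column file.
#' @return A [target_edge_table()].
#' @export
read_target_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(lines[1], "mirna_id\ttarget_id"))
    lines <- lines[-1]
  if (!length(lines)) {
    warning("empty target edge file: ", path)
    return(target_edge_table(data.frame(mirna_id = character(),
                                        target_id = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2))
    stop("wrong column count (expected 2) at line ", which(nf != 2)[1],
         " of ", path)
  tab <- target_edge_table(data.frame(
    mirna_id = vapply(parts, `[`, "", 1),
    target_id = vapply(parts, `[`, "", 2),
    stringsAsFactors = FALSE))
  nd <- attr(tab, "n_duplicates_dropped")
  if (nd > 0) message("read_target_edges: dropped ", nd, " duplicate edge(s)")
  tab
}

#' Write a target edge table to TSV
#' @param x A [target_edge_table()].
#' @param path Output path.
#' @export
write_target_edges <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network as a SIF-like three-column edge list
#'
#' Rows are `(source, interaction, target)` sorted lexicographically, so
#' rewriting the same network is byte-identical. Interaction labels:
#' `"cerna"` for lncRNA-mRNA pairs, `"targets"` for miRNA-partner edges,
#' `"coexp"` for correlation edges.
#'
#' @param network A `cerna_network` (see [build_cerna_network()]) or a
#'   data.frame with columns `source`, `interaction`, `target`.
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  df <- if (inherits(network, "cerna_network")) network$edges
        else as.data.frame(network)
  if (!all(c("source", "interaction", "target") %in% names(df)))
    stop("edge list needs columns source, interaction, target")
  df <- df[, c("source", "interaction", "target")]
  df <- df[order(df$source, df$interaction, df$target), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("source\tinteraction\ttarget", con)
  if (nrow(df))
    writeLines(paste(df$source, df$interaction, df$target, sep = "\t"), con)
  invisible(path)
}

#' Read a SIF-like edge list written by [write_edge_list()]
#' @param path Path to the three-column TSV.
#' @return Data.frame with columns `source`, `interaction`, `target`.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_strict(path)
  if (!identical(names(df), c("source", "interaction", "target")))
    stop("malformed edge list header in ", path)
  df
}

#' Read a GMT gene-set file
#'
#' Standard GMT: each line is `name<TAB>description<TAB>member...`.
#' Duplicate set names or empty sets are rejected; duplicated members are
#' deduplicated with a warning.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short))
    stop("GMT line ", which(short)[1], " has no members")
  nm <- vapply(parts, `[`, "", 1)
  desc <- vapply(parts, `[`, "", 2)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene set collection as GMT
#' @param x A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(x, path) {
  desc <- attr(x, "descriptions")
  lines <- vapply(names(x), function(nm)
    paste(c(nm, desc[[nm]], x[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
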