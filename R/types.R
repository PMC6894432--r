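.ROLES <- c("mRNA", "lncRNA", "miRNA")
.UNITS <- c("counts", "CPM", "FPKM", "log2CPM", "log2FPKM")
.LOG_UNITS <- c("log2CPM", "log2FPKM")

#' Expression matrix container
#'
#' A genes-by-samples numeric matrix tagged with the molecular role of its
#' rows (mRNA, lncRNA or miRNA) and the abundance unit of its cells.
#' Identifiers must be unique, values finite, and non-negative unless the
#' unit is a log2 unit.
#'
#' @param values Numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids).
#' @param role One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param unit One of `"counts"`, `"CPM"`, `"FPKM"`, `"log2CPM"`,
#'   `"log2FPKM"`.
#' @return An object of class `expr_matrix`: the matrix with `role` and
#'   `unit` attributes.
#' @export
expression_matrix <- function(values, role, unit) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  role <- match.arg(role, .ROLES)
  unit <- match.arg(unit, .UNITS)
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(gid))
    stop("duplicate gene id(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at gene '", gid[bad[1]], "', sample '",
         sid[bad[2]], "'")
  }
  if (!(unit %in% .LOG_UNITS) && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative value at gene '", gid[bad[1]], "', sample '",
         sid[bad[2]], "' (unit '", unit, "' requires values >= 0)")
  }
  structure(values, role = role, unit = unit,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d %s gene(s) x %d sample(s) [%s]\n",
              nrow(x), attr(x, "role"), ncol(x), attr(x, "unit")))
  invisible(x)
}

expr_role <- function(x) attr(x, "role")
expr_unit <- function(x) attr(x, "unit")

#' Retag an expression matrix after a manual transformation
#'
#' @param x An `expr_matrix`.
#' @param values Optional replacement matrix (defaults to `x`).
#' @param unit Optional replacement unit tag.
#' @keywords internal
retag <- function(x, values = NULL, unit = NULL) {
  expression_matrix(if (is.null(values)) unclass_mat(x) else values,
                    role = expr_role(x),
                    unit = if (is.null(unit)) expr_unit(x) else unit)
}

unclass_mat <- function(x) {
  attr(x, "role") <- NULL; attr(x, "unit") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' Clinical sample table
#'
#' Per-sample clinical annotation: condition (tumor/normal), optional
#' tumor/normal pairing, optional TNM stage, optional survival follow-up.
#' Each `pair_id` must occur on exactly one tumor and one normal sample,
#' and `event` must be present whenever `survival_time` is.
#'
#' @param df A data.frame with columns `sample_id`, `patient_id`,
#'   `condition` and optionally `pair_id`, `tnm_stage`, `survival_time`,
#'   `event`. Missing optional columns are added as `NA`.
#' @return A validated data.frame of class `clinical_table`.
#' @export
clinical_table <- function(df) {
  req <- c("sample_id", "patient_id", "condition")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing clinical column(s): ",
                         paste(miss, collapse = ", "))
  opt <- c("pair_id", "tnm_stage", "survival_time", "event")
  for (cc in setdiff(opt, names(df))) df[[cc]] <- NA
  df <- df[, c(req, opt)]
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  df$condition <- as.character(df$condition)
  df$pair_id <- as.character(df$pair_id)
  df$tnm_stage <- as.character(df$tnm_stage)
  df$survival_time <- as.numeric(df$survival_time)
  df$event <- as.integer(df$event)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$condition %in% c("tumor", "normal")))
    stop("condition must be 'tumor' or 'normal'")
  ok_stage <- is.na(df$tnm_stage) | df$tnm_stage %in% c("I", "II", "III", "IV")
  if (!all(ok_stage)) stop("tnm_stage must be one of I, II, III, IV")
  has_t <- !is.na(df$survival_time)
  if (any(has_t & is.na(df$event)))
    stop("event must be present whenever survival_time is present: ",
         paste(df$sample_id[has_t & is.na(df$event)], collapse = ", "))
  if (any(df$survival_time[has_t] < 0)) stop("survival_time must be >= 0")
  if (!all(is.na(df$event) | df$event %in% 0:1))
    stop("event must be 0 (censored) or 1 (death)")
  paired <- df[!is.na(df$pair_id), ]
  if (nrow(paired)) {
    tab <- table(paired$pair_id, factor(paired$condition,
                                        levels = c("tumor", "normal")))
    bad <- rownames(tab)[tab[, "tumor"] != 1 | tab[, "normal"] != 1]
    if (length(bad))
      stop("pair_id(s) without exactly one tumor and one normal sample: ",
           paste(bad, collapse = ", "))
  }
  structure(df, class = c("clinical_table", "data.frame"))
}

#' miRNA-to-target predicted binding edge table
#'
#' Directed miRNA -> gene edges (an RNA22-style prediction table).
#' Duplicated rows are dropped; the number dropped is kept in the
#' `"n_duplicates_dropped"` attribute.
#'
#' @param df Data.frame with character columns `mirna_id`, `target_id`.
#' @return Deduplicated data.frame of class `target_edge_table`.
#' @export
target_edge_table <- function(df) {
  if (!all(c("mirna_id", "target_id") %in% names(df)))
    stop("target edge table needs columns mirna_id, target_id")
  df <- data.frame(mirna_id = as.character(df$mirna_id),
                   target_id = as.character(df$target_id),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(!nzchar(df$mirna_id) | !nzchar(df$target_id)))
    stop("empty id in target edge table")
  n0 <- nrow(df)
  df <- unique(df)
  rownames(df) <- NULL
  structure(df, n_duplicates_dropped = n0 - nrow(df),
            class = c("target_edge_table", "data.frame"))
}

#' Map targets to their miRNA regulators (or miRNAs to their targets)
#'
#' @param edges A `target_edge_table`.
#' @param by `"target"` for target -> miRNA-set, `"mirna"` for
#'   miRNA -> target-set.
#' @return Named list of character vectors.
#' @export
edge_map <- function(edges, by = c("target", "mirna")) {
  by <- match.arg(by)
  if (!nrow(edges)) return(list())
  if (by == "target") split(edges$mirna_id, edges$target_id)
  else split(edges$target_id, edges$mirna_id)
}

#' Gene set collection (GMT semantics)
#'
#' @param sets Named list of character vectors (unique names, non-empty
#'   sets; members deduplicated with a warning).
#' @param descriptions Optional character vector parallel to `sets`.
#' @return List of class `gene_set_collection` with a `descriptions`
#'   attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  dup <- vapply(sets, anyDuplicated, 0L) > 0
  if (any(dup)) {
    warning("duplicated members deduplicated in set(s): ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions,
            class = c("gene_set_collection", "list"))
}
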