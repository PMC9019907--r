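#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample identifiers and
#' gene identifiers in the first column (GEO series-matrix style). Values
#' are assumed to be on the log2 scale already; set `log2_transform = TRUE`
#' for raw-scale input, which applies `log2(x + 1)`.
#'
#' @param path file path.
#' @param drop_missing drop genes containing missing values instead of
#'   raising an error.
#' @param log2_transform apply `log2(x + 1)` after reading.
#' @return numeric matrix with gene row names and sample column names, in
#'   file order.
#' @export
read_expression <- function(path, drop_missing = FALSE,
                            log2_transform = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs gene IDs plus >= 1 sample")
  gene_ids <- as.character(df[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene ID(s) in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  sample_ids <- colnames(df)[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    stop("duplicate sample ID(s) in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      stop("non-numeric value in ", path, " at row ",
           if (length(bad)) bad[1L] else "?", ", column '",
           sample_ids[j], "'")
    }
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- gene_ids
  if (anyNA(mat)) {
    if (!drop_missing) {
      stop("missing values in ", path,
           "; use drop_missing = TRUE to drop affected genes")
    }
    keep <- rowSums(is.na(mat)) == 0L
    warning("dropped ", sum(!keep), " gene(s) with missing values")
    mat <- mat[keep, , drop = FALSE]
  }
  if (any(!is.finite(mat))) stop("non-finite expression values in ", path)
  if (log2_transform) mat <- log2(mat + 1)
  mat
}

#' Write an expression matrix to TSV
#'
#' Values are serialized with 17 significant digits so that a
#' write/read round trip reproduces the doubles exactly.
#'
#' @param expr numeric matrix, genes x samples, dimnames set.
#' @param path output file path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1L, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t")
  })
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

.norm_token <- function(x, allowed, warn_counter) {
  x <- trimws(tolower(as.character(x)))
  x[x %in% c("", "na", "nan", "unknown", "missing", "n/a")] <- NA_character_
  key <- tolower(allowed)
  out <- allowed[match(x, key)]
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) warn_counter$n <- warn_counter$n + sum(bad)
  out
}

#' Read a clinical table from TSV
#'
#' Required columns: `sample_id`, `os_months`, `os_event`. Optional:
#' `rfs_months`, `rfs_event`, `age_group`, `sex`, `smoking`, `alcohol`,
#' `t_class`, `n_class`, `stage`, `hpv`, `radiotherapy`. Category tokens
#' are normalized case-insensitively; unrecognized tokens become missing
#' and are counted in a single warning.
#'
#' @param path file path.
#' @return data.frame, one row per sample, with attribute
#'   `n_unknown_tokens` giving the number of unrecognized category cells.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "os_months", "os_event")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) {
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample IDs in clinical table")
  }
  for (tc in intersect(c("os_months", "rfs_months"), colnames(df))) {
    v <- df[[tc]]
    if (any(!is.na(v) & v < 0)) stop("negative times in column ", tc)
  }
  for (ec in intersect(c("os_event", "rfs_event"), colnames(df))) {
    v <- df[[ec]]
    if (any(!is.na(v) & !(v %in% c(0, 1)))) {
      stop("event flags in ", ec, " must be 0/1")
    }
  }
  enums <- list(
    age_group = c("<60", ">=60"), sex = c("male", "female"),
    smoking = c("yes", "no"), alcohol = c("yes", "no"),
    t_class = c("T1-T2", "T3-T4"), n_class = c("N0", "N1-3"),
    stage = c("I-II", "III-IV"), hpv = c("pos", "neg"),
    radiotherapy = c("yes", "no")
  )
  counter <- new.env()
  counter$n <- 0L
  for (nm in intersect(names(enums), colnames(df))) {
    df[[nm]] <- .norm_token(df[[nm]], enums[[nm]], counter)
  }
  if (counter$n > 0L) {
    warning(counter$n, " unrecognized category token(s) set to missing")
  }
  attr(df, "n_unknown_tokens") <- counter$n
  df
}

#' Read per-sample anchor-gene mutation status from TSV
#'
#' Required columns: `sample_id`, `mutated` (0/1).
#'
#' @param path file path.
#' @return data.frame with `sample_id` and integer `mutated`.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "mutated"), colnames(df))
  if (length(miss)) {
    stop("mutation table missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample IDs in mutation table")
  }
  if (any(!(df$mutated %in% c(0, 1)))) {
    stop("mutation status must be binary 0/1")
  }
  df$mutated <- as.integer(df$mutated)
  df[, c("sample_id", "mutated")]
}

#' Write a simple one-row-per-sample table to TSV
#'
#' Used for clinical tables, mutation tables and risk labels.
#'
#' @param df data.frame with a `sample_id` column.
#' @param path output file path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align expression, clinical and mutation tables on shared samples
#'
#' Restricts all three inputs to the intersection of sample IDs, in a
#' deterministic (sorted) order, and reports how many samples each source
#' lost.
#'
#' @param expr expression matrix (genes x samples).
#' @param clinical clinical data.frame with `sample_id`.
#' @param mutation mutation data.frame with `sample_id`.
#' @return list with `expression`, `clinical`, `mutation` (identical sample
#'   order) and `dropped`, a named count of samples dropped per source.
#' @export
align_cohort <- function(expr, clinical, mutation) {
  ids <- sort(intersect(intersect(colnames(expr), clinical$sample_id),
                        mutation$sample_id))
  if (!length(ids)) stop("no samples shared by expression/clinical/mutation")
  dropped <- c(
    expression = ncol(expr) - length(ids),
    clinical = nrow(clinical) - length(ids),
    mutation = nrow(mutation) - length(ids)
  )
  list(
    expression = expr[, ids, drop = FALSE],
    clinical = clinical[match(ids, clinical$sample_id), , drop = FALSE],
    mutation = mutation[match(ids, mutation$sample_id), , drop = FALSE],
    dropped = dropped
  )
}

SIGNATURE_SCHEMA_VERSION <- "1.0"

#' Write / read a signature gene set as JSON
#'
#' Lossless round trip of the anchor gene, per-gene selection statistics
#' and the thresholds used. The file carries a schema version; reading a
#' file with a different version is an explicit error.
#'
#' @param sig a `fatsig_signature` object from [select_signature()].
#' @param path file path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "fatsig_signature"))
  obj <- list(
    schema_version = SIGNATURE_SCHEMA_VERSION,
    anchor_gene = sig$anchor_gene,
    thresholds = sig$thresholds,
    genes = sig$genes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_signature
#' @return `read_signature()` returns the `fatsig_signature` object.
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("schema_version", "anchor_gene", "thresholds", "genes")) {
    if (is.null(obj[[field]])) {
      stop("signature file missing field '", field, "'")
    }
  }
  if (!identical(obj$schema_version, SIGNATURE_SCHEMA_VERSION)) {
    stop("signature schema version mismatch: file has '",
         obj$schema_version, "', expected '", SIGNATURE_SCHEMA_VERSION, "'")
  }
  genes <- as.data.frame(obj$genes, stringsAsFactors = FALSE)
  if (!nrow(genes)) {
    genes <- data.frame(gene_id = character(), fc = numeric(),
                        log2fc = numeric(), t_stat = numeric(),
                        t_p = numeric(), r = numeric(), r_p = numeric(),
                        n_mut = integer(), n_wt = integer(),
                        stringsAsFactors = FALSE)
  }
  structure(list(anchor_gene = obj$anchor_gene,
                 thresholds = as.list(obj$thresholds),
                 genes = genes),
            class = "fatsig_signature")
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Writes `expression.tsv`, `clinical.tsv`, `mutation.tsv` and, when truth
#' is available, `truth_labels.tsv` and `truth_genes.tsv`.
#'
#' @param cohort a `fatsig_cohort` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fatsig_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    mutation = file.path(dir, "mutation.tsv"),
    truth_labels = file.path(dir, "truth_labels.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv")
  )
  write_expression(cohort$expression, paths["expression"])
  write_table_tsv(cohort$clinical, paths["clinical"])
  write_table_tsv(cohort$mutation, paths["mutation"])
  write_table_tsv(cohort$truth_labels, paths["truth_labels"])
  write_table_tsv(cohort$truth_genes, paths["truth_genes"])
  invisible(paths)
}
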