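#' Read a gene x sample expression matrix
#'
#' Loads a log2-scale expression matrix from TSV or GCT. The first column
#' holds gene symbols, the header row sample identifiers. Rows with any
#' missing value are dropped (count recorded), duplicate gene symbols are
#' collapsed by per-sample median, and the result is validated: unique gene
#' and sample ids, at least 2 genes and 2 samples, no missing values.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (plain matrix) or `"gct"` (version line `#1.2`,
#'   dimension line, and a `Description` column which is discarded).
#' @param log2_transform If `TRUE`, applies `log2(x + 1)` after loading, for
#'   inputs on a raw count/FPKM scale. Default `FALSE`: values are assumed
#'   already log2.
#' @return A numeric matrix (genes x samples) with attributes
#'   `n_dropped_na` (rows removed for missing values) and `n_collapsed`
#'   (duplicate symbol rows merged away).
#' @export
read_expression <- function(path, dialect = c("tsv", "gct"), log2_transform = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("expression file not found: ", path)
  skip <- 0L
  if (dialect == "gct") {
    head2 <- readLines(path, n = 2L)
    if (length(head2) < 2L || !startsWith(head2[[1L]], "#1."))
      stop("malformed GCT header (expected version line '#1.2'): ", path)
    skip <- 2L
  }
  raw <- utils::read.delim(path, header = TRUE, skip = skip, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("malformed header: expected gene column plus sample columns")
  gene_ids <- raw[[1L]]
  raw <- raw[, -1L, drop = FALSE]
  if (dialect == "gct" && tolower(colnames(raw)[1L]) == "description")
    raw <- raw[, -1L, drop = FALSE]
  sample_ids <- colnames(raw)
  if (length(sample_ids) < 2L) stop("dimension error: fewer than 2 samples")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in header")

  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw))
  for (j in seq_len(ncol(raw))) {
    col <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(col) & !is.na(raw[[j]]) &
                   !(trimws(raw[[j]]) %in% c("", "NA", "NaN", "nan")))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' at gene '%s', sample '%s'",
                   raw[[j]][bad[1L]], gene_ids[bad[1L]], sample_ids[j]))
    vals[, j] <- col
  }
  keep <- stats::complete.cases(vals) & !is.nan(rowSums(vals))
  n_dropped <- sum(!keep)
  vals <- vals[keep, , drop = FALSE]
  gene_ids <- gene_ids[keep]

  n_collapsed <- 0L
  if (anyDuplicated(gene_ids)) {
    n_collapsed <- length(gene_ids) - length(unique(gene_ids))
    split_idx <- split(seq_along(gene_ids), factor(gene_ids, levels = unique(gene_ids)))
    vals <- t(vapply(split_idx, function(ii) {
      if (length(ii) == 1L) vals[ii, ] else apply(vals[ii, , drop = FALSE], 2L, stats::median)
    }, numeric(ncol(vals))))
    gene_ids <- names(split_idx)
  }
  if (log2_transform) vals <- log2(vals + 1)
  if (nrow(vals) < 2L) stop("dimension error: fewer than 2 genes after filtering")
  dimnames(vals) <- list(gene_ids, sample_ids)
  structure(vals, n_dropped_na = n_dropped, n_collapsed = n_collapsed)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] (tsv dialect): gene symbols in the first
#' column (`gene_id`), one column per sample, full precision.
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

table1_levels <- list(
  gender  = c("Female", "Male"),
  stage   = c("Stage_I", "Stage_II", "Stage_III", "Stage_IV", "Stage_un"),
  t_stage = c("T1", "T2", "T3", "T4", "TX"),
  n_stage = c("N0", "N1", "NX"),
  m_stage = c("M0", "M1", "MX", "M_un"),
  rt      = c("YES", "NO", "UN"),
  tmt     = c("YES", "NO", "UN")
)

#' Read a clinical table
#'
#' TSV with columns `sample_id`, `os_time` (days), `os_event` (0/1) and the
#' categorical covariates `gender`, `stage`, `t_stage`, `n_stage`,
#' `m_stage`, `rt`, `tmt` plus numeric `age` and optional `ips`
#' (immunophenoscore) and `response` columns. Samples with missing survival
#' time or status are excluded (count recorded); category levels are
#' restricted to the cohort-summary vocabulary (an `"unknown"` level is
#' accepted anywhere).
#'
#' @param path Path to a TSV file.
#' @return A data.frame, one row per retained sample, with attribute
#'   `n_dropped_survival`.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(cl))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  keep <- !is.na(cl$os_time) & !is.na(cl$os_event)
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " sample(s) dropped for missing survival fields")
  cl <- cl[keep, , drop = FALSE]
  if (any(cl$os_time < 0)) stop("os_time must be >= 0")
  if (!all(cl$os_event %in% c(0, 1))) stop("os_event must be 0/1")
  if (anyDuplicated(cl$sample_id)) stop("duplicate sample ids in clinical table")
  for (col in intersect(names(table1_levels), colnames(cl))) {
    ok <- cl[[col]] %in% c(table1_levels[[col]], "unknown", NA)
    if (!all(ok))
      stop(sprintf("invalid level(s) in '%s': %s", col,
                   paste(unique(cl[[col]][!ok]), collapse = ", ")))
  }
  attr(cl, "n_dropped_survival") <- n_dropped
  cl
}

#' Summarise a clinical table by category
#'
#' Per-category level counts in the layout of a cohort summary table
#' (category, level, count). Counts within each category sum to the number
#' of rows of `clinical` (missing values are tallied as `"unknown"`).
#'
#' @param clinical Data.frame from [read_clinical()].
#' @param categories Character vector of columns to summarise.
#' @return Data.frame with columns `category`, `level`, `count`.
#' @export
clinical_summary <- function(clinical,
                             categories = c("os_event", "gender", "stage", "t_stage",
                                            "n_stage", "m_stage", "rt", "tmt")) {
  categories <- intersect(categories, colnames(clinical))
  out <- lapply(categories, function(cat) {
    x <- as.character(clinical[[cat]])
    x[is.na(x)] <- "unknown"
    tab <- table(x)
    data.frame(category = cat, level = names(tab), count = as.integer(tab),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Read a cohort summary fixture (category / level / count TSV)
#'
#' @param path TSV with columns `category`, `level`, `count`.
#' @return Data.frame with those columns; counts validated as non-negative
#'   integers.
#' @export
read_clinical_summary <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("category", "level", "count")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("summary missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("counts must be non-negative integers")
  df
}

#' MAF-standard variant classifications counted as nonsilent
#' @return Character vector of classification strings.
#' @export
maf_nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

maf_known_classes <- function() {
  c(maf_nonsilent_classes(),
    "Silent", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "RNA", "IGR",
    "Targeted_Region", "De_novo_Start_InFrame", "De_novo_Start_OutOfFrame")
}

#' Read a MAF (Mutation Annotation Format) file
#'
#' Tab-separated, one row per variant; lines starting with `#` are skipped.
#' Requires `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`; `Chromosome` and `Start_Position` are kept when
#' present, further columns are ignored.
#'
#' @param path Path to a MAF v2.4-compatible file.
#' @return Data.frame with columns `sample_id`, `hugo_symbol`,
#'   `variant_classification`, `chromosome`, `start_position`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE, quote = "")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("MAF missing mandatory column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    sample_id = df$Tumor_Sample_Barcode,
    hugo_symbol = df$Hugo_Symbol,
    variant_classification = df$Variant_Classification,
    chromosome = if ("Chromosome" %in% colnames(df)) as.character(df$Chromosome) else NA_character_,
    start_position = if ("Start_Position" %in% colnames(df)) as.integer(df$Start_Position) else NA_integer_,
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$start_position) & out$start_position < 1L))
    stop("MAF positions must be >= 1 (1-based inclusive)")
  out
}

#' Write variant records as a MAF file
#' @param maf Data.frame as returned by [read_maf()].
#' @param path Output path.
#' @export
write_maf <- function(maf, path) {
  df <- data.frame(Hugo_Symbol = maf$hugo_symbol,
                   Chromosome = maf$chromosome,
                   Start_Position = maf$start_position,
                   Variant_Classification = maf$variant_classification,
                   Tumor_Sample_Barcode = maf$sample_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#' Genes are deduplicated within a set.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("GMT format error: line ", short[1L], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  structure(sets, descriptions = stats::setNames(vapply(fields, `[[`, "", 2L), names(sets)))
}

#' Write gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an immune-cell signature (basis) matrix
#'
#' TSV of marker genes x cell types on a non-log linear scale, as used for
#' deconvolution (LM22-style). Values must be non-negative with no all-zero
#' marker row.
#'
#' @param path TSV path; first column marker gene symbols.
#' @param expected_types Required number of cell-type columns (default 22);
#'   `NULL` skips the check.
#' @return Numeric matrix, markers x cell types.
#' @export
read_signature_matrix <- function(path, expected_types = 22L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (!is.null(expected_types) && ncol(mat) != expected_types)
    stop(sprintf("signature matrix has %d cell types, expected %d", ncol(mat), expected_types))
  if (anyDuplicated(genes)) stop("duplicate marker genes in signature matrix")
  if (any(mat < 0)) stop("signature matrix values must be >= 0")
  if (any(rowSums(mat) == 0)) stop("signature matrix contains an all-zero marker row")
  mat
}

#' Write a signature matrix as TSV
#' @param sig Numeric matrix, markers x cell types.
#' @param path Output path.
#' @export
write_signature_matrix <- function(sig, path) {
  df <- data.frame(gene_id = rownames(sig), sig, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
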