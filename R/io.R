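#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column
#' (log2-scale abundance, log2(TPM+1) convention). Duplicate gene rows are
#' collapsed by their mean. Use `orientation = "samples_by_genes"` for
#' transposed files.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param orientation `"genes_by_samples"` (default) or `"samples_by_genes"`.
#' @return Numeric matrix, genes x samples, with unique rownames.
#' @export
read_expression_tsv <- function(path, orientation = c("genes_by_samples",
                                                      "samples_by_genes")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("expression file '", path, "' is empty or lacks data columns")
  }
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))[1L]
      if (!is.na(bad) || anyNA(vn)) {
        bad <- if (is.na(bad)) which(is.na(vn))[1L] else bad
        stop("non-numeric value '", v[bad], "' at row id '", ids[bad],
             "', column '", colnames(vals)[j], "'")
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "samples_by_genes") m <- t(m)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing value for gene '", rownames(m)[idx[1L]], "', sample '",
         colnames(m)[idx[2L]], "'")
  }
  collapse_duplicate_genes(m)
}

#' @keywords internal
collapse_duplicate_genes <- function(m) {
  if (anyDuplicated(rownames(m))) {
    m <- rowsum(m, group = rownames(m), reorder = FALSE) /
      as.vector(table(rownames(m))[unique(rownames(m))])
  }
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; values are written at full precision.
#'
#' @param m Genes x samples numeric matrix.
#' @param path Output path.
#' @param id_column Name for the gene-id column.
#' @export
write_expression_tsv <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM to TPM
#'
#' Per sample j, `TPM[i, j] = FPKM[i, j] / sum_i FPKM[i, j] * 1e6`, so each
#' column of the result sums to one million.
#'
#' @param fpkm Non-negative genes x samples matrix of FPKM values (raw scale,
#'   not log).
#' @return Matrix of TPM values with the same dimnames.
#' @export
fpkm_to_tpm <- function(fpkm) {
  stopifnot(is.matrix(fpkm), is.numeric(fpkm))
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  tot <- colSums(fpkm)
  if (any(tot == 0)) {
    stop("all-zero column(s): ",
         paste(utils::head(colnames(fpkm)[tot == 0], 5L), collapse = ", "))
  }
  sweep(fpkm, 2L, tot, "/") * 1e6
}

#' Read gene sets in GMT format
#'
#' Broad dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are dropped (order preserved).
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; the description lines are kept in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file '", path, "' is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("GMT line ", which(bad)[1L], " has fewer than 3 fields (no genes)")
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  writeLines(mapply(function(nm, d, genes) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(sets), description, sets), path)
  invisible(path)
}

#' Read a per-sample clinical table from TSV
#'
#' Requires columns `sample_id`, `os_time` (months, strictly positive) and
#' `os_event` (0/1). Any further columns are carried along as covariates
#' (e.g. `response`, `subtype`, age, sex).
#'
#' @param path Path to a TSV file with a header.
#' @return `data.frame` with one row per sample.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' @keywords internal
validate_clinical <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  }
  if (!is.numeric(df$os_time) || anyNA(df$os_time) || any(df$os_time <= 0)) {
    bad <- df$sample_id[which(!is.finite(df$os_time) | df$os_time <= 0)][1L]
    stop("os_time must be strictly positive; offending sample: ", bad)
  }
  if (!all(df$os_event %in% c(0, 1))) {
    bad <- df$sample_id[which(!df$os_event %in% c(0, 1))][1L]
    stop("os_event must be 0 or 1; offending sample: ", bad)
  }
  df
}

#' Controlled vocabulary of mutation variant classes
#' @export
maf_variant_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
    "Frame_Shift_Del", "Splice_Site", "In_Frame_Ins", "In_Frame_Del",
    "Nonstop_Mutation", "Translation_Start_Site", "Silent", "Other")
}

#' Default nonsilent variant classes used for tumor mutation burden
#' @export
nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
    "Frame_Shift_Del", "Splice_Site", "In_Frame_Ins", "In_Frame_Del")
}

#' Read a MAF-lite mutation table
#'
#' Only the three MAF columns `Tumor_Sample_Barcode`, `Hugo_Symbol` and
#' `Variant_Classification` are required; extra columns are ignored. Classes
#' outside the controlled vocabulary are kept with class `"Other"` (warning).
#' Duplicate (sample, gene, class) rows are permitted — multiple hits.
#'
#' @param path Path to a TSV file with a header.
#' @return `data.frame` with columns `sample_id`, `gene`, `variant_class`.
#' @export
read_maf_lite <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("MAF-lite missing required column(s): ", paste(miss, collapse = ", "))
  }
  out <- data.frame(sample_id = as.character(df$Tumor_Sample_Barcode),
                    gene = as.character(df$Hugo_Symbol),
                    variant_class = as.character(df$Variant_Classification),
                    stringsAsFactors = FALSE)
  unknown <- !out$variant_class %in% maf_variant_classes()
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unknown variant class (e.g. '",
            out$variant_class[unknown][1L], "') recoded to 'Other'")
    out$variant_class[unknown] <- "Other"
  }
  out
}

#' Write a MAF-lite mutation table
#' @param mutations `data.frame` with `sample_id`, `gene`, `variant_class`.
#' @param path Output path.
#' @export
write_maf_lite <- function(mutations, path) {
  df <- data.frame(Tumor_Sample_Barcode = mutations$sample_id,
                   Hugo_Symbol = mutations$gene,
                   Variant_Classification = mutations$variant_class)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a cohort to the samples shared by all tables
#'
#' Intersects sample ids across the expression matrix, the clinical table and
#' (if given) the mutation table; sample order follows the expression matrix.
#' Mutation records for dropped samples are removed, but a sample need not
#' have mutations to be kept.
#'
#' @param expr Genes x samples matrix.
#' @param clinical Clinical `data.frame` (see [read_clinical_tsv()]).
#' @param mutations Optional mutation `data.frame` (see [read_maf_lite()]);
#'   its samples do not constrain the intersection.
#' @return List with `expr`, `clinical`, `mutations` (NULL if not given) and
#'   `dropped` (count of samples discarded from each input).
#' @export
align_cohort <- function(expr, clinical, mutations = NULL) {
  keep <- intersect(colnames(expr), clinical$sample_id)
  if (length(keep) == 0L) {
    stop("no samples shared between expression and clinical tables")
  }
  keep <- colnames(expr)[colnames(expr) %in% keep]
  dropped <- c(expression = ncol(expr) - length(keep),
               clinical = nrow(clinical) - length(keep))
  expr <- expr[, keep, drop = FALSE]
  clinical <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  if (!is.null(mutations)) {
    n0 <- nrow(mutations)
    mutations <- mutations[mutations$sample_id %in% keep, , drop = FALSE]
    rownames(mutations) <- NULL
    dropped <- c(dropped, mutation_records = n0 - nrow(mutations))
  }
  if (any(dropped > 0)) {
    message("align_cohort: dropped ",
            paste(names(dropped), dropped, sep = "=", collapse = ", "))
  }
  list(expr = expr, clinical = clinical, mutations = mutations,
       dropped = dropped)
}
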