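# ---- domain containers -------------------------------------------------------

#' Construct an expression matrix with a declared layout
#'
#' The package passes expression data around as a plain numeric matrix
#' (genes in rows, samples in columns) carrying a `layout` attribute that
#' declares the measurement scale: raw `counts`, `fpkm`-like normalized
#' abundances, or `log2`-transformed values. Constructors and readers enforce
#' the container invariants: unique gene and sample identifiers, finite or
#' `NA` values, and non-negative integral values for the counts layout.
#'
#' @param values Numeric matrix with rownames (genes) and colnames (samples).
#' @param layout One of `"counts"`, `"fpkm"`, `"log2"`.
#' @return The matrix with a `layout` attribute set.
#' @export
expression_matrix <- function(values, layout = c("fpkm", "counts", "log2")) {
  layout <- match.arg(layout)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA")
  if (layout == "counts") {
    v <- values[!is.na(values)]
    if (any(v < 0) || any(v != round(v)))
      stop("counts layout requires non-negative integral values")
  }
  attr(values, "layout") <- layout
  values
}

#' Layout tag of an expression matrix
#' @param mat Matrix created by [expression_matrix()] or a reader.
#' @return Character scalar, or `NA` if untagged.
#' @export
expr_layout <- function(mat) {
  l <- attr(mat, "layout")
  if (is.null(l)) NA_character_ else l
}

# ---- expression TSV ----------------------------------------------------------

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers and one row per gene, first
#' column holding the gene identifier. Duplicate gene rows are resolved by
#' `dup_policy`: `"error"` (default, safest when the matrix feeds a gene
#' signature), `"max"` (elementwise maximum) or `"mean"`.
#'
#' @param path TSV file path.
#' @param layout Declared layout of the stored values (see [expression_matrix()]).
#' @param dup_policy How to collapse duplicated gene rows.
#' @return Expression matrix with `layout` attribute.
#' @export
read_expression_matrix <- function(path, layout = c("fpkm", "counts", "log2"),
                                   dup_policy = c("error", "max", "mean")) {
  layout <- match.arg(layout)
  dup_policy <- match.arg(dup_policy)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("no data rows in ", path)
  genes <- tab[[1L]]
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(NULL, samples)))
  bad <- which(is.na(vals) & !(raw %in% c("NA", "", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at gene row %d, sample column '%s': '%s'",
                 bad[1L, 1L], samples[bad[1L, 2L]], raw[bad[1L, , drop = FALSE]]))
  if (anyDuplicated(genes)) {
    if (dup_policy == "error")
      stop("duplicate gene rows: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "),
           " (set dup_policy to 'max' or 'mean' to collapse)")
    f <- if (dup_policy == "max") function(x) max(x, na.rm = TRUE) else
      function(x) mean(x, na.rm = TRUE)
    ugenes <- unique(genes)
    collapsed <- t(vapply(ugenes, function(g) {
      apply(vals[genes == g, , drop = FALSE], 2L, f)
    }, numeric(ncol(vals))))
    vals <- collapsed
    genes <- ugenes
  }
  rownames(vals) <- genes
  expression_matrix(vals, layout)
}

#' Write an expression matrix to TSV
#' @param mat Expression matrix.
#' @param path Output path.
#' @param id_column Name for the gene-id column.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- MAF ---------------------------------------------------------------------

#' Variant classes treated as synonymous
#' @export
SYNONYMOUS_CLASSES <- c("Silent", "Synonymous_Variant")

#' Variant classes recognised as somatic (beyond the synonymous set)
#' @keywords internal
KNOWN_VARIANT_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
  "Translation_Start_Site", "Nonstop_Mutation",
  "Silent", "Synonymous_Variant"
)

#' Read a MAF-subset mutation table
#'
#' Requires columns `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`; `Chromosome`, `Start_Position`,
#' `t_ref_count` and `t_alt_count` are used when present. Unknown variant
#' classes are kept verbatim and flagged in the `known_class` column.
#'
#' @param path TSV path.
#' @return A `data.frame` with columns `sample_id`, `gene`,
#'   `variant_classification`, `chrom`, `position`, `ref_count`, `alt_count`,
#'   `synonymous`, `known_class`.
#' @export
read_maf <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_col <- setdiff(need, colnames(tab))
  if (length(missing_col) > 0L)
    stop("MAF is missing mandatory column(s): ", paste(missing_col, collapse = ", "))
  get_num <- function(col) if (col %in% colnames(tab))
    suppressWarnings(as.numeric(tab[[col]])) else rep(NA_real_, nrow(tab))
  mut <- data.frame(
    sample_id = as.character(tab$Tumor_Sample_Barcode),
    gene = as.character(tab$Hugo_Symbol),
    variant_classification = as.character(tab$Variant_Classification),
    chrom = if ("Chromosome" %in% colnames(tab)) as.character(tab$Chromosome) else NA_character_,
    position = get_num("Start_Position"),
    ref_count = get_num("t_ref_count"),
    alt_count = get_num("t_alt_count"),
    stringsAsFactors = FALSE
  )
  both <- !is.na(mut$ref_count) & !is.na(mut$alt_count)
  if (any(both & (mut$ref_count + mut$alt_count) <= 0))
    stop("record with ref_count + alt_count <= 0")
  mut$synonymous <- mut$variant_classification %in% SYNONYMOUS_CLASSES
  mut$known_class <- mut$variant_classification %in% KNOWN_VARIANT_CLASSES
  if (any(!mut$known_class))
    warning("unknown variant classification(s) kept verbatim: ",
            paste(unique(mut$variant_classification[!mut$known_class]), collapse = ", "))
  mut
}

#' Write a mutation table as a MAF-subset TSV
#' @param mut Mutation table (as from [read_maf()]).
#' @param path Output path.
#' @export
write_maf <- function(mut, path) {
  out <- data.frame(
    Hugo_Symbol = mut$gene,
    Tumor_Sample_Barcode = mut$sample_id,
    Variant_Classification = mut$variant_classification,
    Chromosome = mut$chrom,
    Start_Position = mut$position,
    t_ref_count = mut$ref_count,
    t_alt_count = mut$alt_count,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GMT ---------------------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' ignored; genes repeated within a line are deduplicated.
#'
#' @param path GMT path.
#' @return Named list of character vectors (gene symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(fields)))
    nm <- fields[[1L]]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop(sprintf("GMT line %d ('%s') has no genes", i, nm))
    sets[[nm]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# ---- IRPM printed signature --------------------------------------------------

#' Load the published 47-gene IRPM signature
#'
#' Returns the signed marker-gene signature of the immune-related prognostic
#' model as published: 35 genes positively correlated with prognostic
#' immune-cell infiltration and 12 negatively correlated genes. The signature
#' is shipped with the package as a GMT fixture.
#'
#' @return An `irpm_signature` object: list with character vectors `positive`
#'   and `negative`, `source = "table1"`.
#' @export
load_table1_signature <- function() {
  path <- system.file("extdata", "irpm_signature_table1.gmt", package = "latgc",
                      mustWork = TRUE)
  sets <- read_gmt(path)
  irpm_signature(sets[["IRPM_positive"]], sets[["IRPM_negative"]],
                 source = "table1")
}

#' Construct a signed IRPM signature
#' @param positive,negative Disjoint non-empty character vectors of gene symbols.
#' @param source `"constructed"` or `"table1"`.
#' @param meta Optional list of selection metadata (chosen cells, correlations).
#' @return `irpm_signature` object.
#' @export
irpm_signature <- function(positive, negative, source = "constructed", meta = NULL) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  if (length(positive) == 0L || length(negative) == 0L)
    stop("both signature sides must be non-empty")
  if (length(intersect(positive, negative)) > 0L)
    stop("positive and negative gene sets must be disjoint")
  structure(list(positive = positive, negative = negative,
                 source = source, meta = meta),
            class = "irpm_signature")
}

#' @export
print.irpm_signature <- function(x, ...) {
  cat(sprintf("IRPM signature (%s): %d positive, %d negative genes\n",
              x$source, length(x$positive), length(x$negative)))
  invisible(x)
}

# ---- clinical ----------------------------------------------------------------

#' Read a clinical table
#'
#' Requires `sample_id`, `os_time` (days, non-negative) and `os_event`
#' (0 = censored, 1 = death). A numeric `latitude_deg` column and categorical
#' factors (stage, grade, response, gender, ...) are carried through when
#' present; empty strings in categorical columns become `NA`.
#'
#' @param path TSV path.
#' @return `data.frame`, one row per sample.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  validate_clinical(tab)
}

#' Validate a clinical table
#' @param tab data.frame with at least sample_id, os_time, os_event.
#' @return The validated table.
#' @export
validate_clinical <- function(tab) {
  need <- c("sample_id", "os_time", "os_event")
  missing_col <- setdiff(need, colnames(tab))
  if (length(missing_col) > 0L)
    stop("clinical table missing column(s): ", paste(missing_col, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in clinical table")
  tab$os_time <- as.numeric(tab$os_time)
  tab$os_event <- as.numeric(tab$os_event)
  if (any(!is.na(tab$os_time) & tab$os_time < 0))
    stop("negative os_time")
  ev <- tab$os_event[!is.na(tab$os_event)]
  if (any(!ev %in% c(0, 1)))
    stop("os_event outside {0, 1}")
  if ("latitude_deg" %in% colnames(tab))
    tab$latitude_deg <- as.numeric(tab$latitude_deg)
  for (col in setdiff(colnames(tab), c("sample_id", "os_time", "os_event", "latitude_deg"))) {
    if (is.character(tab[[col]])) tab[[col]][!nzchar(trimws(tab[[col]]))] <- NA
  }
  tab
}

#' Write a clinical table to TSV
#' @param tab Clinical data.frame.
#' @param path Output path.
#' @export
write_clinical <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
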