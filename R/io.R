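# Readers and writers for the three table kinds the pipeline consumes:
# log2 expression matrices (genes x samples), clinical tables, gene panels,
# and long-format qPCR well tables. Expression is assumed already log2-scale
# and normalized; nothing here rescales.

sep_for <- function(path, dialect = NULL) {
  if (!is.null(dialect)) {
    return(switch(dialect, tsv = "\t", csv = ",",
                  stop("unknown dialect: ", dialect)))
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a log2 expression matrix
#'
#' Expects delimited text with gene identifiers in the first column and a
#' header row of sample identifiers. Duplicated gene rows are collapsed by
#' their mean (with a message); duplicated sample columns are rejected.
#' `NA` cells are kept as missing values; any other non-numeric cell is a
#' parse error reported with its row/column coordinates.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`; default inferred from the extension.
#' @param platform_tag free-text platform annotation stored as an attribute.
#' @return numeric matrix, genes x samples, with `platform_tag` attribute.
#' @export
read_expression <- function(path, dialect = NULL, platform_tag = "") {
  raw <- read.delim(path, sep = sep_for(path, dialect), check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("expression file needs >= 2 sample columns")
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  gene_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | toupper(vals) == "NA"), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at gene row %d ('%s'), sample column '%s'",
                 bad[1, 1], gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  }
  m <- matrix(num, nrow = nrow(vals), dimnames = list(gene_ids, sample_ids))
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    decif_log("collapsing %d duplicated gene id(s) by mean: %s",
              length(dup), paste(dup, collapse = ", "))
    m <- rowsum(m, group = gene_ids, reorder = FALSE, na.rm = TRUE) /
      rowsum((!is.na(m)) * 1, group = gene_ids, reorder = FALSE)
  }
  validate_expression(m)
  attr(m, "platform_tag") <- platform_tag
  m
}

#' Validate an expression matrix
#'
#' @param expr numeric matrix, genes x samples, dimnames required.
#' @param allow_missing allow `NA` entries (they are only ever imputed inside
#'   scoring operations, never persisted).
#' @return the matrix, invisibly.
#' @export
validate_expression <- function(expr, allow_missing = TRUE) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (nrow(expr) < 2 || ncol(expr) < 2) stop("need >= 2 genes and >= 2 samples")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  if (!allow_missing && anyNA(expr)) stop("missing values not allowed here")
  if (any(is.infinite(expr))) stop("non-finite expression values")
  invisible(expr)
}

#' Write an expression matrix as delimited text
#' @param expr genes x samples matrix.
#' @param path output path; dialect inferred from extension.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = sep_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene panel
#'
#' A panel is a gene list with the expected modulation direction: +1 means
#' over-expressed in signature-positive samples, -1 under-expressed.
#'
#' @param genes character vector of unique gene ids.
#' @param directions +1/-1 per gene (default all +1).
#' @param name panel name.
#' @return tibble with columns `gene`, `direction` and a `name` attribute.
#' @export
gene_panel <- function(genes, directions = rep(1L, length(genes)), name = "panel") {
  if (length(genes) == 0) stop("empty gene panel")
  if (anyDuplicated(genes)) stop("duplicate genes in panel")
  if (!all(directions %in% c(-1L, 1L))) stop("directions must be +1 or -1")
  if (length(directions) != length(genes)) stop("one direction per gene")
  p <- tibble::tibble(gene = as.character(genes), direction = as.integer(directions))
  attr(p, "name") <- name
  p
}

#' Read a gene panel from a two-column delimited file (gene, direction)
#' @param path file path; a missing direction column defaults to +1.
#' @param name panel name (default: file base name).
#' @export
read_gene_panel <- function(path, name = NULL) {
  df <- read.delim(path, sep = sep_for(path), stringsAsFactors = FALSE)
  dir <- if ("direction" %in% names(df)) df$direction else rep(1L, nrow(df))
  gene_panel(df$gene, as.integer(dir),
             name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a gene panel
#' @param panel gene panel tibble.
#' @param path output path.
#' @export
write_gene_panel <- function(panel, path) {
  write.table(panel, path, sep = sep_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

er_alias <- c("+" = "+", "-" = "-", "pos" = "+", "neg" = "-",
              "positive" = "+", "negative" = "-", "1" = "+", "0" = "-")
pam50_levels <- c("Basal", "Her2", "LumA", "LumB", "Normal")

#' Read a clinical table
#'
#' Required columns: `sample_id`, `os_time` (months, time from surgery to
#' death from any cause), `os_event` (0/1). Optional: `age`, `tumor_size`
#' (mm), `er`, `pgr` (+/- with documented aliases), `pam50`
#' (Basal/Her2/LumA/LumB/Normal), `grade`.
#'
#' @param path file path.
#' @return validated tibble.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, sep = sep_for(path), stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Validate (and type) a clinical table
#' @param df data frame with the columns of [read_clinical()].
#' @export
validate_clinical <- function(df) {
  required <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) stop("missing required clinical column(s): ",
                             paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  if (any(!is.finite(df$os_time)) || any(df$os_time < 0)) {
    stop("os_time must be finite and >= 0")
  }
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0 or 1")
  for (col in c("er", "pgr")) {
    if (col %in% names(df)) {
      key <- tolower(as.character(df[[col]]))
      key[df[[col]] %in% c("+", "-")] <- df[[col]][df[[col]] %in% c("+", "-")]
      mapped <- unname(er_alias[key])
      if (anyNA(mapped[!is.na(df[[col]])])) {
        stop("unknown ", col, " category: ",
             paste(unique(df[[col]][is.na(mapped) & !is.na(df[[col]])]), collapse = ", "))
      }
      df[[col]] <- mapped
    }
  }
  if ("pam50" %in% names(df)) {
    bad <- setdiff(unique(df$pam50[!is.na(df$pam50)]), pam50_levels)
    if (length(bad) > 0) stop("unknown pam50 category: ", paste(bad, collapse = ", "))
    df$pam50 <- factor(df$pam50, levels = pam50_levels)
  }
  tibble::as_tibble(df)
}

#' Write a clinical table
#' @param df clinical tibble.
#' @param path output path.
#' @export
write_clinical <- function(df, path) {
  write.table(df, path, sep = sep_for(path), quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Inner-join expression and clinical tables on sample id
#'
#' Samples present in only one input are dropped with a logged report; the
#' reader contract is that no row disappears silently.
#'
#' @param expr genes x samples matrix.
#' @param clinical clinical tibble.
#' @return list with the aligned `expr`, `clinical`, and `dropped` ids.
#' @export
join_cohort <- function(expr, clinical) {
  common <- intersect(colnames(expr), clinical$sample_id)
  dropped <- union(setdiff(colnames(expr), common),
                   setdiff(clinical$sample_id, common))
  if (length(dropped) > 0) {
    decif_log("inner join dropped %d sample(s): %s", length(dropped),
              paste(dropped, collapse = ", "))
  }
  if (length(common) == 0) stop("no samples shared between expression and clinical")
  list(expr = expr[, common, drop = FALSE],
       clinical = clinical[match(common, clinical$sample_id), ],
       dropped = dropped)
}

#' Read a long-format qPCR well table
#'
#' Columns: `plate_id`, `well_type` (`sample`/`calibrator`/`blank`),
#' `sample_id`, `gene_id`, `replicate`, `cq` (cycles; `NA` = undetermined).
#'
#' @param path file path.
#' @return validated tibble of wells.
#' @export
read_qpcr <- function(path) {
  df <- read.delim(path, sep = sep_for(path), stringsAsFactors = FALSE)
  validate_qpcr(df)
}

#' Validate a qPCR well table
#' @param df well table as in [read_qpcr()].
#' @export
validate_qpcr <- function(df) {
  required <- c("plate_id", "well_type", "sample_id", "gene_id", "replicate", "cq")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) stop("missing qPCR column(s): ", paste(miss, collapse = ", "))
  if (!all(df$well_type %in% c("sample", "calibrator", "blank"))) {
    stop("well_type must be sample/calibrator/blank")
  }
  ok <- is.na(df$cq) | (df$cq > 0 & df$cq <= 40)
  if (!all(ok)) stop("Cq values must lie in (0, 40] or be NA (undetermined)")
  tibble::as_tibble(df)
}

#' Write a qPCR well table
#' @param df well tibble.
#' @param path output path.
#' @export
write_qpcr <- function(df, path) {
  write.table(df, path, sep = sep_for(path), quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
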