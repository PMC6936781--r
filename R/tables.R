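#' Construct a genus-level abundance table
#'
#' The abundance table is the X block of the pipeline: a samples-by-taxa
#' matrix of non-negative counts or relative abundances, with per-sample
#' fermentation day and an optional group label. Samples-as-rows is the
#' internal orientation everywhere; readers normalise to it at the boundary.
#'
#' @param values numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids character vector of unique sample labels (default:
#'   rownames of `values`).
#' @param taxon_ids character vector of unique genus labels (default:
#'   colnames). Labels are opaque strings; no taxonomy parsing is attempted.
#' @param day integer fermentation day per sample (>= 1), or `NULL`.
#' @param group optional group label per sample.
#' @param proportions logical; declare the values as relative abundances
#'   (each row must then sum to 1 within 1e-9).
#' @return an object of class `abundance_table`: a list with elements
#'   `values`, `day`, `group`, `proportions`.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            taxon_ids = colnames(values), day = NULL,
                            group = NULL, proportions = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon ids: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (length(sample_ids) != nrow(values) || length(taxon_ids) != ncol(values))
    stop("id lengths do not match the value matrix")
  if (anyNA(values)) stop("missing values are not allowed in abundance tables")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 sample_ids[bad[1]], taxon_ids[bad[2]]))
  }
  dimnames(values) <- list(sample_ids, taxon_ids)
  if (!is.null(day)) {
    day <- as.integer(day)
    if (length(day) != nrow(values) || any(day < 1L))
      stop("'day' must give one integer >= 1 per sample")
  }
  if (!is.null(group) && length(group) != nrow(values))
    stop("'group' must give one label per sample")
  if (proportions) {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-9))
      stop("table declared as proportions but row sums deviate from 1 (max |dev| = ",
           format(max(abs(rs - 1))), ")")
  }
  structure(list(values = values, day = day, group = group,
                 proportions = proportions),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$proportions) "proportions" else "counts"))
  cat("samples:", paste(utils::head(rownames(x$values), 8), collapse = ", "),
      if (nrow(x$values) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Construct a flavor-component table
#'
#' The flavor table is the Y block: samples by flavor components
#' (volatile flavor compounds, VF, and free amino acids, AA), with a
#' per-component annotation giving the kind and, for VFs, the chemical
#' category, and for AAs the taste class.
#'
#' @param values non-negative numeric matrix, samples in rows, components in
#'   columns. Missing values are an error, not imputed.
#' @param sample_ids,component_ids unique labels (default: dimnames).
#' @param annotation data.frame with columns `component_id`, `kind`
#'   (`"VF"`/`"AA"`), `category` (VF chemical category), `taste_class`
#'   (AA taste class). Every component in `values` must be annotated.
#' @return an object of class `flavor_table` with elements `values`,
#'   `annotation`.
#' @export
flavor_table <- function(values, sample_ids = rownames(values),
                         component_ids = colnames(values), annotation) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  component_ids <- as.character(component_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(component_ids)) stop("duplicate component ids")
  if (anyNA(values))
    stop("missing flavor intensities are not allowed (no imputation rule)")
  if (any(values < 0)) stop("negative flavor intensity")
  dimnames(values) <- list(sample_ids, component_ids)
  annotation <- validate_annotation(annotation)
  missing_ann <- setdiff(component_ids, annotation$component_id)
  if (length(missing_ann))
    stop("components without annotation: ", paste(missing_ann, collapse = ", "))
  annotation <- annotation[match(component_ids, annotation$component_id), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  structure(list(values = values, annotation = annotation),
            class = "flavor_table")
}

#' @export
print.flavor_table <- function(x, ...) {
  k <- table(x$annotation$kind)
  cat(sprintf("flavor_table: %d samples x %d components (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(k), k), collapse = ", ")))
  invisible(x)
}

#' @export
dim.flavor_table <- function(x) dim(x$values)

vf_categories <- c("alcohol", "ester", "pyrazine", "alkane", "aldehyde",
                   "phenol", "acid", "other")
aa_classes <- c("umami", "sweet", "bitter", "unclassified")

validate_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  need <- c("component_id", "kind")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (!"category" %in% names(annotation)) annotation$category <- NA_character_
  if (!"taste_class" %in% names(annotation))
    annotation$taste_class <- NA_character_
  annotation$component_id <- as.character(annotation$component_id)
  if (anyDuplicated(annotation$component_id))
    stop("duplicate component ids in annotation")
  if (!all(annotation$kind %in% c("VF", "AA")))
    stop("annotation 'kind' must be 'VF' or 'AA'")
  vf <- annotation$kind == "VF"
  if (any(vf & (is.na(annotation$category) |
                !annotation$category %in% vf_categories)))
    stop("every VF needs a category in {",
         paste(vf_categories, collapse = ", "), "}")
  aa <- annotation$kind == "AA"
  bad_class <- aa & !is.na(annotation$taste_class) &
    !annotation$taste_class %in% aa_classes
  if (any(bad_class))
    stop("unknown AA taste class: ",
         paste(unique(annotation$taste_class[bad_class]), collapse = ", "))
  annotation
}

#' Packaged flavor-component annotation
#'
#' The annotation shipped with the package: 42 volatile flavor compounds in
#' eight chemical categories (2 alcohols, 14 esters, 5 pyrazines, 3 alkanes,
#' 4 aldehydes, 3 phenols, 6 acids, 5 others) plus 16 free amino acids with
#' taste classes (umami: Glu, Asp; sweet: Ala, Gly, Ser, Thr; bitter: Arg,
#' His, Ile, Leu, Met, Trp, Tyr, Val; Lys and Phe unclassified).
#'
#' @return annotation data.frame (see [flavor_table()]).
#' @export
douchi_flavor_annotation <- function() {
  path <- system.file("extdata", "flavor_annotation.tsv", package = "fermcore")
  read_flavor_annotation(path)
}

#' Read a flavor annotation table
#'
#' @param path TSV with columns component_id, kind, category, taste_class
#'   (extra columns such as `name` are kept).
#' @return validated annotation data.frame.
#' @export
read_flavor_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA", check.names = FALSE)
  validate_annotation(ann)
}

read_numeric_table <- function(path, sep) {
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  labels <- as.character(raw[[1]])
  body <- raw[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) & !anyNA(v)) {
        i <- which(is.na(num))[1]
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s' of %s",
                     v[i], labels[i], names(body)[j], path))
      }
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- labels
  m
}

#' Read an abundance table from TSV (or CSV)
#'
#' One header row, one label column, numeric body. The orientation flag says
#' whether rows are samples or taxa in the file; internally the table is
#' always samples-as-rows.
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default) or `"taxa_as_rows"`.
#' @param proportions declare the table as relative abundances.
#' @param csv read comma-separated instead of tab-separated.
#' @return [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_as_rows",
                                                 "taxa_as_rows"),
                                 proportions = FALSE, csv = FALSE) {
  orientation <- match.arg(orientation)
  m <- read_numeric_table(path, if (csv) "," else "\t")
  if (orientation == "taxa_as_rows") m <- t(m)
  abundance_table(m, proportions = proportions)
}

#' Write an abundance table as TSV
#'
#' Deterministic column order (as stored); samples as rows.
#' @param x abundance_table.
#' @param path output path.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  write_matrix_tsv(x$values, path, label = "sample_id")
}

#' Read a flavor table from TSV
#'
#' @param path samples-by-components TSV, one label column.
#' @param annotation annotation data.frame or path to one (default: the
#'   packaged annotation).
#' @param csv comma-separated input.
#' @return [flavor_table()].
#' @export
read_flavor_table <- function(path, annotation = douchi_flavor_annotation(),
                              csv = FALSE) {
  if (is.character(annotation)) annotation <- read_flavor_annotation(annotation)
  m <- read_numeric_table(path, if (csv) "," else "\t")
  flavor_table(m, annotation = annotation)
}

#' Write a flavor table as TSV
#' @param x flavor_table.
#' @param path output path.
#' @export
write_flavor_table <- function(x, path) {
  stopifnot(inherits(x, "flavor_table"))
  write_matrix_tsv(x$values, path, label = "sample_id")
}

write_matrix_tsv <- function(m, path, label = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Each sample (row) is divided by its total; zeros stay zero. Idempotent on
#' tables already declared as proportions.
#'
#' @param t abundance_table.
#' @return abundance_table with `proportions = TRUE`.
#' @export
to_relative_abundance <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  rs <- rowSums(t$values)
  if (any(rs == 0))
    stop("all-zero sample(s): ",
         paste(rownames(t$values)[rs == 0], collapse = ", "))
  abundance_table(t$values / rs, day = t$day, group = t$group,
                  proportions = TRUE)
}

#' Mean relative abundance per taxon with low-abundance pooling
#'
#' Reports each taxon's mean relative abundance across samples; taxa whose
#' mean falls below `threshold` are pooled into an `"other"` row, so the
#' reported abundances plus `"other"` sum to 1 per sample.
#'
#' @param t abundance_table of proportions.
#' @param threshold pooling threshold in `[0, 1)`; 0 disables pooling.
#' @return data.frame with columns `taxon`, `mean_abundance`, and one column
#'   per sample; the `"other"` row last (when pooling applies).
#' @export
abundance_summary <- function(t, threshold = 0.01) {
  stopifnot(inherits(t, "abundance_table"))
  if (!t$proportions) t <- to_relative_abundance(t)
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  mean_ab <- colMeans(t$values)
  keep <- mean_ab >= threshold
  if (threshold == 0) keep[] <- TRUE
  named <- t$values[, keep, drop = FALSE]
  out <- data.frame(taxon = colnames(named),
                    mean_abundance = colMeans(named),
                    t(named), check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (any(!keep)) {
    other <- rowSums(t$values[, !keep, drop = FALSE])
    out <- rbind(out, data.frame(taxon = "other",
                                 mean_abundance = mean(other),
                                 t(matrix(other, ncol = 1,
                                          dimnames = list(names(other), NULL))),
                                 check.names = FALSE))
  }
  out <- out[order(-out$mean_abundance), , drop = FALSE]
  if ("other" %in% out$taxon)  # keep the pooled row last
    out <- rbind(out[out$taxon != "other", ], out[out$taxon == "other", ])
  rownames(out) <- NULL
  out
}

# internal: extract the numeric block from a table or plain matrix
block_values <- function(x, as_proportions = FALSE) {
  if (inherits(x, "abundance_table")) {
    if (as_proportions && !x$proportions) x <- to_relative_abundance(x)
    x$values
  } else if (inherits(x, "flavor_table")) {
    x$values
  } else {
    as.matrix(x)
  }
}
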