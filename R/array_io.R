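#' @name array_io
#' @title Tabular formats used by the pipeline
#' @description Readers and writers for the plain-text dialects the pipeline
#'   touches: tab-separated slide tables (one spot per row, two-channel
#'   foreground/background intensities), the experiment-design table mapping
#'   slides to patients / dye-swap pairs / orientations, and GMT-style gene
#'   sets. All readers validate strictly and report offending rows.
NULL

slide_table_columns <- c("spot_id", "gene_id",
                         "ch1_fg", "ch1_bg", "ch2_fg", "ch2_bg")
design_columns <- c("slide_id", "patient_id", "pair_id", "orientation")
orientation_levels <- c("patient_in_ch1", "patient_in_ch2")

#' Validate a slide table
#'
#' Checks the column set, uniqueness of `spot_id`, and that every intensity
#' is finite and nonnegative.
#'
#' @param slide data frame with columns `spot_id`, `gene_id`, `ch1_fg`,
#'   `ch1_bg`, `ch2_fg`, `ch2_bg`.
#' @param where label used in error messages (e.g. a file path).
#' @return the slide table, invisibly, if valid.
#' @export
validate_slide_table <- function(slide, where = "slide table") {
  missing_cols <- setdiff(slide_table_columns, names(slide))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s) %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  dup <- duplicated(slide$spot_id)
  if (any(dup))
    stop(sprintf("%s: duplicate spot_id '%s' at row %d", where,
                 slide$spot_id[which(dup)[1]], which(dup)[1]), call. = FALSE)
  for (col in c("ch1_fg", "ch1_bg", "ch2_fg", "ch2_bg")) {
    v <- slide[[col]]
    if (!is.numeric(v))
      stop(sprintf("%s: column %s is not numeric", where, col), call. = FALSE)
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop(sprintf("%s: negative or non-finite %s at row %d", where, col,
                   bad[1]), call. = FALSE)
  }
  invisible(slide)
}

#' Read a slide table (TSV)
#'
#' Dialect: tab-separated, header
#' `spot_id gene_id ch1_fg ch1_bg ch2_fg ch2_bg`, decimal point, no
#' thousands separators. Row order is preserved.
#'
#' @param path file path.
#' @return validated slide table (data frame).
#' @export
read_slide_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_slide_table(tab, where = path)
}

#' Write a slide table (TSV)
#' @param slide validated slide table.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_slide_table <- function(slide, path) {
  validate_slide_table(slide)
  utils::write.table(slide[, slide_table_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an experiment-design table (TSV)
#'
#' Dialect: tab-separated, header
#' `slide_id patient_id pair_id orientation` with orientation one of
#' `patient_in_ch1` / `patient_in_ch2`. Every pair must consist of exactly
#' two slides with opposite orientations.
#'
#' @param path file path.
#' @return validated design data frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_design(d, where = path)
}

#' Validate an experiment design
#' @param design data frame with design columns.
#' @param where label for error messages.
#' @return the design, invisibly, if valid.
#' @export
validate_design <- function(design, where = "design") {
  missing_cols <- setdiff(design_columns, names(design))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s) %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (any(duplicated(design$slide_id)))
    stop(sprintf("%s: duplicate slide_id", where), call. = FALSE)
  bad_or <- !design$orientation %in% orientation_levels
  if (any(bad_or))
    stop(sprintf("%s: unknown orientation '%s' at row %d", where,
                 design$orientation[which(bad_or)[1]], which(bad_or)[1]),
         call. = FALSE)
  for (pr in unique(design$pair_id)) {
    sub <- design[design$pair_id == pr, ]
    if (nrow(sub) != 2L || length(unique(sub$orientation)) != 2L)
      stop(sprintf(
        "%s: pair '%s' must have exactly 2 slides with opposite orientations",
        where, pr), call. = FALSE)
    if (length(unique(sub$patient_id)) != 1L)
      stop(sprintf("%s: pair '%s' spans multiple patients", where, pr),
           call. = FALSE)
  }
  invisible(design)
}

#' Write an experiment-design table (TSV)
#' @param design validated design data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.table(design[, design_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT-style gene-set file
#'
#' Each line: `set_id <TAB> description <TAB> member1 <TAB> member2 ...`.
#' Duplicate members within a set are removed with a warning; a line with
#' fewer than three fields is an error.
#'
#' @param path file path.
#' @return named list of class `"gene_set_collection"`; each element has
#'   `description` and `members`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("%s: line %d has %d field(s); need set_id, description, >=1 member",
                   path, i, length(fields)), call. = FALSE)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s': duplicate members removed", fields[1]),
              call. = FALSE)
      members <- unique(members)
    }
    if (length(members) == 0L)
      stop(sprintf("%s: line %d: set '%s' has no members", path, i, fields[1]),
           call. = FALSE)
    sets[[fields[1]]] <- list(description = fields[2], members = members)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param sets a `gene_set_collection`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$description, sets[[id]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ratio matrix with per-gene status
#' @param rm ratio-matrix object from [build_ratio_matrix()] /
#'   [pattern_consistency_filter()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_ratio_matrix <- function(rm, path) {
  tab <- data.frame(gene_id = rownames(rm$values),
                    rm$values,
                    status = rm$status,
                    direction = rm$direction,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
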