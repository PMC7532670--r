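#' Read a slide manifest
#'
#' Reads a cohort manifest listing one H&E slide per row. The manifest must
#' contain a `slide_id` column and at least one molecular label source:
#' `msisensor_score` (tumour-normal sequencing MSI score) or `unstable_loci`
#' (number of unstable loci out of the five-locus PCR panel). Optional columns
#' (`cohort`, `image_dir`, `annotation_xml`, `n_patches`) are carried through;
#' missing optional fields become `NA`.
#'
#' @param path Path to a TSV or CSV manifest (UTF-8, header row).
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A tibble with one row per slide and columns `slide_id`, `cohort`,
#'   `msisensor_score`, `unstable_loci`, `ms_label` (filled by a labelling
#'   rule, `NA` on return), `n_patches`, `split`.
#' @seealso [label_from_msisensor()], [label_from_loci()], [stratified_split()]
#' @export
read_slide_manifest <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_pathomsi(paste0("manifest not found: ", path))
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", fileEncoding = "UTF-8")
  if (!"slide_id" %in% names(raw)) {
    stop_pathomsi("manifest has no slide_id column")
  }
  if (!any(c("msisensor_score", "unstable_loci", "ms_label") %in% names(raw))) {
    stop_pathomsi("manifest has no label source column (msisensor_score, unstable_loci or ms_label)")
  }
  raw$slide_id <- as.character(raw$slide_id)
  dup <- unique(raw$slide_id[duplicated(raw$slide_id)])
  if (length(dup) > 0) {
    stop_pathomsi(paste0("duplicated slide_id in manifest: ",
                         paste(dup, collapse = ", ")))
  }
  as_slide_records(raw)
}

#' Normalise a slide table to the canonical record layout
#'
#' Coerces any data frame with a `slide_id` column to the slide-record
#' layout used throughout the package, filling absent optional columns
#' (`cohort`, `msisensor_score`, `unstable_loci`, `ms_label`, `n_patches`,
#' `split`) with `NA`/`"unassigned"` and carrying extra columns through.
#'
#' @param df Data frame with at least `slide_id`.
#' @return A slide-record tibble.
#' @export
as_slide_records <- function(df) {
  df <- as_tibble(df)
  want_num <- function(col) {
    if (col %in% names(df)) as.numeric(df[[col]]) else rep(NA_real_, nrow(df))
  }
  out <- tibble(
    slide_id = as.character(df$slide_id),
    cohort = if ("cohort" %in% names(df)) as.character(df$cohort) else NA_character_,
    msisensor_score = want_num("msisensor_score"),
    unstable_loci = {
      v <- want_num("unstable_loci")
      as.integer(round(v))
    },
    ms_label = if ("ms_label" %in% names(df)) as.character(df$ms_label) else NA_character_,
    n_patches = if ("n_patches" %in% names(df)) as.integer(df$n_patches) else NA_integer_,
    split = if ("split" %in% names(df)) as.character(df$split) else "unassigned"
  )
  extra <- setdiff(names(df), names(out))
  if (length(extra) > 0) out <- dplyr::bind_cols(out, df[extra])
  out
}

#' Label slides from MSIsensor scores
#'
#' Applies the sequencing-based rule used for TCGA-style cohorts: slides with
#' an MSIsensor score at or above the threshold are labelled MSI, all others
#' MSS. The default threshold of 10 is the standard clinical rule.
#'
#' @param records Slide tibble from [read_slide_manifest()].
#' @param threshold Score at or above which a slide is MSI (default 10).
#' @return The records with `ms_label` filled.
#' @export
label_from_msisensor <- function(records, threshold = 10) {
  missing <- records$slide_id[is.na(records$msisensor_score)]
  if (length(missing) > 0) {
    stop_pathomsi(paste0("msisensor_score absent for: ",
                         paste(missing, collapse = ", ")))
  }
  dplyr::mutate(records,
                ms_label = ifelse(.data$msisensor_score >= threshold, "MSI", "MSS"))
}

#' Label slides from the five-locus PCR panel
#'
#' Applies the multiplex PCR-capillary electrophoresis rule: instability in at
#' least `min_unstable` of the five microsatellite loci (BAT-25, BAT-26,
#' D5S346, D2S123, D17S250) labels the slide MSI-H (here `MSI`); MSI-L and MSS
#' are pooled into the negative class `MSS`.
#'
#' @param records Slide tibble.
#' @param min_unstable Minimum unstable loci for an MSI call (default 2).
#' @return The records with `ms_label` filled.
#' @export
label_from_loci <- function(records, min_unstable = 2) {
  v <- records$unstable_loci
  missing <- records$slide_id[is.na(v)]
  if (length(missing) > 0) {
    stop_pathomsi(paste0("unstable_loci absent for: ",
                         paste(missing, collapse = ", ")))
  }
  if (any(v < 0 | v > 5)) {
    stop_pathomsi("unstable_loci must lie in 0..5 (five-locus panel)")
  }
  dplyr::mutate(records,
                ms_label = ifelse(.data$unstable_loci >= min_unstable, "MSI", "MSS"))
}

#' Stratified train/test partition of a labelled cohort
#'
#' Splits a labelled cohort into train and test sets preserving the MSI/MSS
#' class balance (default 7:3). Within each class the train count is the
#' fraction rounded to the nearest integer, ties toward train; membership is
#' a seeded uniform draw, so the partition is reproducible.
#'
#' @param records Labelled slide tibble (every `ms_label` present).
#' @param train_fraction Fraction of each class assigned to train (default 0.7).
#' @param seed Integer seed controlling the draw.
#' @return The records with `split` set to `"train"` or `"test"`.
#' @export
stratified_split <- function(records, train_fraction = 0.7, seed = 1L) {
  if (any(is.na(records$ms_label))) {
    stop_pathomsi("all slides must be labelled before splitting")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_pathomsi("train_fraction must lie in (0,1)")
  }
  counts <- table(records$ms_label)
  if (any(counts < 2)) {
    stop_pathomsi(paste0("each class needs >= 2 slides; got ",
                         paste(names(counts), counts, sep = "=", collapse = ", ")))
  }
  with_seed(seed, {
    records$split <- "test"
    for (cls in names(counts)) {
      idx <- which(records$ms_label == cls)
      n_train <- floor(length(idx) * train_fraction + 0.5)  # ties toward train
      n_train <- max(1L, min(length(idx) - 1L, as.integer(n_train)))
      take <- sample(idx, n_train)
      records$split[take] <- "train"
    }
    records
  })
}

#' Write a partition as a two-column TSV
#'
#' @param records Slide tibble with `split` assigned.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(records, path) {
  utils::write.table(records[, c("slide_id", "split")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
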