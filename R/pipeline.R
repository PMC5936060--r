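# Pipeline orchestration: images -> scores -> genotypes -> statistics.
#
# Each step reads and writes plain files (PNG, ROI JSON, CSV), so the
# quantification step is blind by interface: the scores CSV has no
# genotype column and quantify_clutch() never sees a genotype file.

#' Quantify every embryo in a clutch directory
#'
#' Applies the full densitometry chain per ROI record: read the acquired
#' image, invert, convert to 8-bit grayscale, rasterize both polygons and
#' score.  ROI records without a matching image are skipped with a
#' warning; it is an error when *no* record can be processed.
#'
#' @param images_dir Directory of acquired (un-inverted) PNG/TIFF images,
#'   named `<embryo_id>.<ext>`.
#' @param roi_file ROI JSON (one record per embryo, see [read_roi_json()]).
#' @param out_csv Optional path; when given, the score table is written
#'   there (`embryo_id, signal_mean, background_mean, score,
#'   negative_flag`).
#' @param area_tolerance Passed to [score_embryo()].
#' @return data.frame of per-embryo measurements.
#' @export
quantify_clutch <- function(images_dir, roi_file, out_csv = NULL,
                            area_tolerance = 0.01) {
  rois <- read_roi_json(roi_file)
  rows <- list()
  for (r in rois) {
    hits <- Sys.glob(file.path(images_dir, paste0(r$embryo_id, ".*")))
    hits <- hits[tolower(tools::file_ext(hits)) %in% c("png", "tif", "tiff")]
    if (length(hits) == 0L) {
      warning("no image for embryo ", r$embryo_id, "; skipped", call. = FALSE)
      next
    }
    img <- invert(to_grayscale_8bit(read_image(hits[1])))
    rows[[length(rows) + 1L]] <-
      score_embryo(img, r$signal, r$background, embryo_id = r$embryo_id,
                   area_tolerance = area_tolerance)
  }
  if (length(rows) == 0L) stop("no embryo could be quantified")
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Call genotypes for a table of observed gel bands
#'
#' Builds the expected WT/HET/MUT patterns from an allele pair and calls
#' every sample with [call_genotype()].  Malformed band lists yield
#' `UNKNOWN` for that row, never an error.
#'
#' @param bands Named list of numeric band vectors (see
#'   [read_band_table()]), or a path to the band-table CSV.
#' @param wt,mut Allele sequences (strings, or a FASTA path via
#'   [read_fasta()] upstream).
#' @param enzyme A [restriction_enzyme()].
#' @param tolerance Band-matching tolerance in bp.
#' @param out_csv Optional output CSV path (`sample_id, genotype`).
#' @return data.frame `sample_id`, `genotype`, with the call rate in
#'   attribute `"call_rate"`.
#' @export
genotype_clutch <- function(bands, wt, mut, enzyme, tolerance = 5,
                            out_csv = NULL) {
  if (is.character(bands) && length(bands) == 1L)
    bands <- read_band_table(bands)
  patterns <- expected_band_patterns(wt, mut, enzyme)
  calls <- vapply(bands, function(b) {
    tryCatch(call_genotype(b, patterns, tolerance = tolerance),
             error = function(e) {
               warning("malformed band list: ", conditionMessage(e),
                       call. = FALSE)
               "UNKNOWN"
             })
  }, "")
  out <- data.frame(sample_id = names(bands), genotype = unname(calls),
                    stringsAsFactors = FALSE)
  attr(out, "call_rate") <- mean(calls != "UNKNOWN")
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Merge scores with genotypes and run the statistical analysis
#'
#' Joins the two tables on `embryo_id`/`sample_id` (exact string match;
#' unmatched ids on either side are reported), then fits [ish_fit()].
#' An optional `visual_category` column in the score table adds a
#' category-by-genotype contingency [chi_square()] test.
#'
#' @param scores data.frame from [quantify_clutch()] (or its CSV).
#' @param genotypes data.frame from [genotype_clutch()] (or its CSV).
#' @param ... Passed to [ish_fit()].
#' @return List: `fit` (`"ish_fit"`), `merged` (data.frame),
#'   `unmatched_scores`, `unmatched_genotypes`, and `chi_square` when
#'   visual categories are present.
#' @export
analyze_clutch <- function(scores, genotypes, ...) {
  if (is.character(scores)) scores <- utils::read.csv(scores,
                                                      stringsAsFactors = FALSE)
  if (is.character(genotypes)) genotypes <- utils::read.csv(genotypes,
                                                            stringsAsFactors = FALSE)
  key_g <- if ("sample_id" %in% names(genotypes)) "sample_id" else "embryo_id"
  merged <- merge(scores, genotypes, by.x = "embryo_id", by.y = key_g)
  unmatched_s <- setdiff(scores$embryo_id, genotypes[[key_g]])
  unmatched_g <- setdiff(genotypes[[key_g]], scores$embryo_id)
  if (length(unmatched_s) || length(unmatched_g))
    warning(sprintf("unmatched ids: %d score row(s), %d genotype row(s)",
                    length(unmatched_s), length(unmatched_g)), call. = FALSE)
  if (all(merged$genotype %in% c("UNKNOWN", NA)))
    stop("all genotypes UNKNOWN: nothing to analyse")
  fit <- ish_fit(score ~ genotype, merged, ...)
  out <- list(fit = fit, merged = merged,
              unmatched_scores = unmatched_s,
              unmatched_genotypes = unmatched_g)
  if ("visual_category" %in% names(merged)) {
    keep <- merged$genotype != "UNKNOWN"
    out$chi_square <- chi_square(table(merged$visual_category[keep],
                                       merged$genotype[keep]))
  }
  out
}

#' Read a pipeline config file
#'
#' One YAML file covers generator parameters, enzyme definitions, area
#' tolerance, alpha and target power; every field has the package default.
#'
#' @param path YAML path.
#' @return Config list with class `"ish_config"`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "ish_config")
}
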