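# Synthetic fixtures: embryo-like ISH images with genotype-conditional
# staining, matched ROI files and truth tables; allele pairs whose
# wild-type carries a single restriction site destroyed in the mutant; and
# single-embryo qPCR Ct tables.
#
# Intensity truth is defined post-inversion (dark stain -> high inverted
# intensity), so generator parameters live on the same scale as measured
# background-subtracted scores.  Per-genotype intensities are drawn from
# Normal(mu_g, (cv_g * mu_g)^2) truncated at 0; scores measured from noisy
# images may still dip below 0, as real ones occasionally do.

#' Clutch design: the study conditions for a simulated ISH experiment
#'
#' Defaults mirror a heterozygous incross read out with a probe whose
#' signal halves in homozygous mutants: Mendelian 1:2:1 genotype ratios and
#' the per-genotype means (54, 50.1, 26.3 intensity units) and coefficients
#' of variation (0.24, 0.22, 0.21) observed for dnmt3bb.1 staining in a
#' runx1 mutant clutch.
#'
#' @param n_embryos Number of embryos in the clutch.
#' @param genotype_probabilities Probabilities of WT/HET/MUT, summing to 1.
#' @param mu Named per-genotype mean post-inversion intensity (units of
#'   8-bit intensity).
#' @param cv Named per-genotype coefficient of variation (sd/mean).
#' @param noise_sd Additive Gaussian pixel noise sd (intensity units).
#' @param gradient_amplitude Peak-to-peak linear illumination gradient
#'   across the image width (intensity units).
#' @param height,width Image size in pixels (each >= 128).
#' @param seed Integer seed; the whole clutch is reproducible from it.
#' @return An object of class `"clutch_design"`.
#' @export
clutch_design <- function(n_embryos = 130L,
                          genotype_probabilities = c(WT = 0.25, HET = 0.5,
                                                     MUT = 0.25),
                          mu = c(WT = 54, HET = 50.1, MUT = 26.3),
                          cv = c(WT = 0.24, HET = 0.22, MUT = 0.21),
                          noise_sd = 5,
                          gradient_amplitude = 10,
                          height = 128L, width = 196L,
                          seed = 1L) {
  p <- genotype_probabilities
  if (abs(sum(p) - 1) > 1e-9) stop("genotype probabilities must sum to 1")
  if (is.null(names(p))) names(p) <- c("WT", "HET", "MUT")
  stopifnot(all(mu >= 0), all(cv >= 0), noise_sd >= 0,
            height >= 128L, width >= 128L, n_embryos >= 1L)
  structure(list(n_embryos = as.integer(n_embryos),
                 genotype_probabilities = p, mu = mu, cv = cv,
                 noise_sd = noise_sd,
                 gradient_amplitude = gradient_amplitude,
                 height = as.integer(height), width = as.integer(width),
                 seed = as.integer(seed)),
            class = "clutch_design")
}

#' @export
print.clutch_design <- function(x, ...) {
  cat(sprintf(
    "clutch design: %d embryos, P(WT/HET/MUT) = %s\n  mu = %s, cv = %s\n  noise sd %.3g, gradient %.3g, image %dx%d, seed %d\n",
    x$n_embryos, paste(x$genotype_probabilities, collapse = "/"),
    paste(x$mu, collapse = "/"), paste(x$cv, collapse = "/"),
    x$noise_sd, x$gradient_amplitude, x$width, x$height, x$seed))
  invisible(x)
}

# one truncated-normal intensity draw per embryo; truncation at 0 keeps
# the truth non-negative (measurement noise can still push scores below 0)
draw_intensity <- function(mu, cv, n = 1L) {
  x <- stats::rnorm(n, mu, cv * mu)
  pmax(x, 0)
}

#' Draw per-embryo true staining intensities for a clutch
#'
#' The genotype-conditional intensity model shared by the image renderer:
#' genotypes are multinomial draws from the design probabilities and each
#' intensity is a zero-truncated Normal(mu_g, (cv_g mu_g)^2) draw.  Useful
#' for score-level simulation studies where rendering images adds nothing.
#'
#' @param design A [clutch_design()].
#' @return data.frame `embryo_id`, `true_genotype`, `true_signal_intensity`.
#' @export
simulate_scores <- function(design) {
  stopifnot(inherits(design, "clutch_design"))
  g <- sample(names(design$genotype_probabilities), design$n_embryos,
              replace = TRUE, prob = design$genotype_probabilities)
  data.frame(
    embryo_id = sprintf("embryo_%03d", seq_len(design$n_embryos)),
    true_genotype = g,
    true_signal_intensity = draw_intensity(design$mu[g], design$cv[g],
                                           design$n_embryos),
    stringsAsFactors = FALSE)
}

#' Render one embryo-like ISH image with known staining intensity
#'
#' Draws a light field with an elliptical embryo body, a horizontal
#' "dorsal aorta" stripe whose post-inversion mean intensity over the
#' signal ROI equals `intensity`, additive Gaussian pixel noise and a
#' linear left-to-right illumination gradient.  The signal ROI is a
#' rectangle inside the stripe; the background ROI is the same rectangle
#' translated dorsally (up) into unstained body — equal area by
#' construction.
#'
#' @param design A [clutch_design()].
#' @param intensity True post-inversion staining intensity of this embryo.
#' @param embryo_id Identifier for the ROI record.
#' @return List: `image` (RGB array, un-inverted, as acquired), `roi`
#'   (record with `embryo_id`, `signal`, `background` vertices).
#' @export
generate_embryo_image <- function(design, intensity,
                                  embryo_id = "embryo_001") {
  h <- design$height; w <- design$width
  body_value <- 200    # un-inverted embryo body gray
  field_value <- 235   # un-inverted background field
  cx <- w / 2; cy <- h / 2
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  img <- matrix(field_value, h, w)
  body <- ((xs - cx) / (0.45 * w))^2 + ((ys - cy) / (0.32 * h))^2 <= 1
  img[body] <- body_value
  # stripe: horizontal band through the body midline, below the "notochord"
  stripe_y <- c(cy + 0.08 * h, cy + 0.16 * h)
  stripe_x <- c(cx - 0.30 * w, cx + 0.30 * w)
  stripe <- xs >= stripe_x[1] & xs < stripe_x[2] &
    ys >= stripe_y[1] & ys < stripe_y[2]
  if (stripe_y[2] >= h || stripe_x[2] >= w)
    stop("invalid design: stripe falls outside the image")
  img[stripe] <- body_value - intensity        # darker stain = stronger signal
  # linear illumination gradient across x, zero-mean
  img <- img + design$gradient_amplitude * ((xs / w) - 0.5)
  img <- img + stats::rnorm(length(img), 0, design$noise_sd)
  img[img < 0] <- 0; img[img > 255] <- 255
  img <- round(img)
  rgb <- array(img, dim = c(h, w, 3))
  # ROIs strictly inside the stripe / body, rectangle corners on integers
  sx0 <- ceiling(stripe_x[1]) + 2; sx1 <- floor(stripe_x[2]) - 2
  sy0 <- ceiling(stripe_y[1]) + 1; sy1 <- floor(stripe_y[2]) - 1
  signal <- rbind(c(sx0, sy0), c(sx1, sy0), c(sx1, sy1), c(sx0, sy1))
  dy <- -round(0.22 * h)                       # dorsal, above the stripe
  roi <- list(embryo_id = embryo_id, signal = signal,
              background = translate_roi(signal, 0, dy))
  list(image = rgb, roi = roi)
}

#' Generate a full synthetic clutch on disk
#'
#' Writes one PNG per embryo (un-inverted, as acquired), a combined ROI
#' JSON and a truth CSV (`embryo_id`, `true_genotype`,
#' `true_signal_intensity`).  Fully reproducible from `design$seed`;
#' per-embryo rendering uses sub-streams drawn from one clutch RNG.
#'
#' @param design A [clutch_design()].
#' @param dir Output directory (created).
#' @return Invisibly, the truth data.frame.
#' @export
generate_clutch <- function(design, dir) {
  stopifnot(inherits(design, "clutch_design"))
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(design$seed)
  truth <- simulate_scores(design)
  embryo_seeds <- sample.int(.Machine$integer.max - 1L, design$n_embryos)
  rois <- vector("list", design$n_embryos)
  for (i in seq_len(design$n_embryos)) {
    set.seed(embryo_seeds[i])
    e <- generate_embryo_image(design, truth$true_signal_intensity[i],
                               truth$embryo_id[i])
    write_image(e$image,
                file.path(dir, "images", paste0(truth$embryo_id[i], ".png")))
    rois[[i]] <- e$roi
  }
  write_roi_json(rois, file.path(dir, "rois.json"))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}

#' Construct a wild-type/mutant allele pair for an RFLP assay
#'
#' Builds a random amplicon of `total_length` bases containing exactly one
#' recognition site for `enzyme`, positioned so that complete digestion
#' yields `cut_fragments`; the mutant allele destroys that site either by a
#' single substitution (length preserved — a nonsense point mutation) or by
#' a k-bp deletion spanning the site (as in a TALEN-induced frameshift).
#' Both alleles are verified by digestion before being returned; sequences
#' that acquire a spurious site are rejected and redrawn.
#'
#' @param total_length Wild-type amplicon length (bp).
#' @param enzyme A [restriction_enzyme()].
#' @param cut_fragments Two fragment lengths summing to `total_length`.
#' @param mutation `"substitution"` or `"deletion"`.
#' @param deletion_k Deletion size in bp (used when `mutation = "deletion"`).
#' @param max_tries Bounded retries before giving up.
#' @return List `wt`, `mut` of sequence strings.
#' @export
generate_allele_pair <- function(total_length, enzyme, cut_fragments,
                                 mutation = c("substitution", "deletion"),
                                 deletion_k = 5L, max_tries = 200L) {
  mutation <- match.arg(mutation)
  stopifnot(length(cut_fragments) == 2L,
            sum(cut_fragments) == total_length)
  site_len <- nchar(enzyme$site)
  cut_at <- cut_fragments[1]                   # cut between cut_at, cut_at+1
  start <- cut_at - enzyme$cut_offset + 1L     # 1-based site start
  if (start < 1L || start + site_len - 1L > total_length)
    stop("cut_fragments place the recognition site outside the sequence")
  site_seq <- concrete_site(enzyme)
  for (try in seq_len(max_tries)) {
    bases <- sample(c("A", "C", "G", "T"), total_length, replace = TRUE)
    bases[seq.int(start, start + site_len - 1L)] <-
      strsplit(site_seq, "")[[1]]
    wt <- paste(bases, collapse = "")
    if (length(find_sites(wt, enzyme)) != 1L) next
    mut <- if (mutation == "substitution") {
      b <- bases
      # break the first non-degenerate site base by substitution
      pos <- start + which.min(vapply(
        strsplit(enzyme$site, "")[[1]],
        function(code) length(IUPAC_SETS[[code]]), numeric(1))) - 1L
      b[pos] <- setdiff(c("A", "C", "G", "T"), b[pos])[1]
      paste(b, collapse = "")
    } else {
      del <- seq.int(start, start + deletion_k - 1L)
      paste(bases[-del], collapse = "")
    }
    if (length(find_sites(mut, enzyme)) == 0L)
      return(list(wt = wt, mut = mut))
  }
  stop("allele construction failed after ", max_tries,
       " tries (spurious sites kept appearing)")
}

# one concrete realisation of a degenerate site (first base of each set)
concrete_site <- function(enzyme) {
  paste(vapply(strsplit(enzyme$site, "")[[1]],
               function(code) IUPAC_SETS[[code]][1], ""), collapse = "")
}

#' Generate a synthetic single-embryo qPCR Ct table
#'
#' Per embryo, triplicate Ct values for a housekeeping gene and a target
#' gene are drawn so that the embryo-level delta-Ct (mean target Ct minus
#' mean housekeeping Ct) is exactly Normal(`dct_mean`, `dct_sd`^2):
#' replicate deviations are centred within each triplicate so technical
#' replicate scatter never perturbs the embryo-level value.
#'
#' @param n_per_group Named integer vector: embryos per group.
#' @param dct_means,dct_sds Named per-group delta-Ct mean and sd (cycles).
#' @param replicates Technical replicates per gene (default 3).
#' @param rep_sd Within-triplicate replicate scatter sd (cycles).
#' @param hk_mean,hk_sd Housekeeping-gene Ct level across embryos.
#' @param target Target gene name; `housekeeping` reference gene name.
#' @param housekeeping Reference gene name.
#' @return data.frame in long Ct-table form: `embryo_id`, `group`, `gene`,
#'   `ct1`..`ct<replicates>`.
#' @export
generate_qpcr_table <- function(n_per_group, dct_means, dct_sds,
                                replicates = 3L, rep_sd = 0.15,
                                hk_mean = 18, hk_sd = 0.3,
                                target = "runx1",
                                housekeeping = "eef1a1l1") {
  stopifnot(all(n_per_group >= 2L),
            identical(names(n_per_group), names(dct_means)),
            identical(names(n_per_group), names(dct_sds)))
  rows <- list()
  k <- 0L
  centred <- function(n, sd) { e <- stats::rnorm(n, 0, sd); e - mean(e) }
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      k <- k + 1L
      id <- sprintf("%s_%02d", g, i)
      hk <- stats::rnorm(1, hk_mean, hk_sd)
      dct <- stats::rnorm(1, dct_means[[g]], dct_sds[[g]])
      hk_reps <- hk + centred(replicates, rep_sd)
      tg_reps <- hk + dct + centred(replicates, rep_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        embryo_id = id, group = g, gene = housekeeping,
        t(stats::setNames(hk_reps, paste0("ct", seq_len(replicates)))),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        embryo_id = id, group = g, gene = target,
        t(stats::setNames(tg_reps, paste0("ct", seq_len(replicates)))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
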