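# Independent brute-force oracles, deliberately naive and separate from
# the implementation paths they check.

iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# every window tested one base at a time; returns 0-based cut positions
oracle_find_sites <- function(seq, site, cut_offset) {
  b <- strsplit(seq, "")[[1]]
  p <- strsplit(site, "")[[1]]
  cuts <- integer(0)
  for (s in seq_len(length(b) - length(p) + 1L)) {
    ok <- TRUE
    for (j in seq_along(p)) {
      base <- b[s + j - 1L]
      if (base == "N" || !(base %in% iupac_sets_oracle[[p[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) cuts <- c(cuts, s - 1L + cut_offset)
  }
  cuts
}

oracle_digest <- function(seq, site, cut_offset) {
  cuts <- oracle_find_sites(seq, site, cut_offset)
  cuts <- cuts[cuts > 0 & cuts < nchar(seq)]
  sort(diff(c(0L, sort(cuts), nchar(seq))), decreasing = TRUE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# scalar even-odd point-in-polygon by explicit ray casting
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > py) != (v[j, 2] > py)) {
      xint <- (v[j, 1] - v[i, 1]) * (py - v[i, 2]) /
        (v[j, 2] - v[i, 2]) + v[i, 1]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# per-pixel loop: mean intensity of pixels whose centers fall in polygon
oracle_mean_intensity <- function(img, v) {
  total <- 0; count <- 0L
  for (y in seq_len(nrow(img)) - 1L) for (x in seq_len(ncol(img)) - 1L) {
    if (oracle_point_in_polygon(x + 0.5, y + 0.5, v)) {
      total <- total + img[y + 1L, x + 1L]
      count <- count + 1L
    }
  }
  total / count
}

# random simple polygon: convex hull of random points (guaranteed simple)
random_polygon <- function(h, w, n_pts = 6) {
  repeat {
    x <- runif(n_pts, 1, w - 1); y <- runif(n_pts, 1, h - 1)
    hull <- chull(x, y)
    if (length(hull) >= 3) return(cbind(x[hull], y[hull]))
  }
}

random_gray_image <- function(h, w)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
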