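# In-silico PCR, restriction digestion and RFLP genotype calling.
#
# Sequences are plain uppercase character strings over {A,C,G,T,N}; an
# enzyme is a recognition pattern in IUPAC code plus the top-strand cut
# offset within that pattern.  Only top-strand cut coordinates are used:
# gel band sizes are insensitive to sticky-end overhangs.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Restriction enzyme definition
#'
#' @param name Enzyme name (e.g. `"HaeII"`).
#' @param site Recognition site in IUPAC code (e.g. `"RGCGCY"`).
#' @param cut_offset Top-strand cut position within the site: the enzyme
#'   cuts between site base `cut_offset` and `cut_offset + 1` (0 = before
#'   the first base, `nchar(site)` = after the last).
#' @return An object of class `"restriction_enzyme"`.
#' @examples
#' haeii <- restriction_enzyme("HaeII", "RGCGCY", 5)
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  site <- toupper(as.character(site))
  codes <- strsplit(site, "")[[1]]
  bad <- setdiff(codes, names(IUPAC_SETS))
  if (length(bad) > 0)
    stop("invalid IUPAC code(s) in recognition site: ",
         paste(bad, collapse = ", "))
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(site))
    stop("cut_offset must lie within 0..", nchar(site))
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  s <- strsplit(x$site, "")[[1]]
  cat(sprintf("%s: %s^%s\n", x$name,
              paste(s[seq_len(x$cut_offset)], collapse = ""),
              paste(s[-seq_len(x$cut_offset)], collapse = "")))
  invisible(x)
}

#' Built-in genotyping enzymes
#'
#' `HaeII` (RGCGC^Y) genotypes the runx1 W84X allele; `SacII` (CCGC^GG)
#' genotypes the lmo4a 5 bp deletion.  Offsets follow the standard REBASE
#' top-strand convention.
#' @return A named list of [restriction_enzyme()] objects.
#' @export
genotyping_enzymes <- function() {
  list(HaeII = restriction_enzyme("HaeII", "RGCGCY", 5L),
       SacII = restriction_enzyme("SacII", "CCGCGG", 4L))
}

#' Load enzyme definitions from a structured config block
#'
#' @param x A list of lists with fields `name`, `site`, `cut_offset`
#'   (e.g. parsed from the `enzymes:` block of a YAML config).
#' @return Named list of [restriction_enzyme()] objects.
#' @export
enzymes_from_config <- function(x) {
  out <- lapply(x, function(e)
    restriction_enzyme(e$name, e$site, e$cut_offset))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

canonical_sequence <- function(seq) {
  seq <- toupper(gsub("[ \t\r\n]", "", as.character(seq)))
  if (nchar(seq) < 1L) stop("empty sequence")
  bad <- setdiff(strsplit(seq, "")[[1]], c("A", "C", "G", "T", "N"))
  if (length(bad) > 0)
    stop("sequence contains non-ACGTN characters: ",
         paste(unique(bad), collapse = ", "))
  seq
}

#' Match a window against an IUPAC-degenerate pattern
#'
#' A window base matches a pattern code iff it belongs to the code's
#' degeneracy set (R = A/G, Y = C/T, N = any, ...).  An `N` in the
#' *sequence* never matches any code — unknown bases must not create
#' phantom restriction sites.
#'
#' @param pattern IUPAC pattern string.
#' @param window Base string of the same length.
#' @return `TRUE` or `FALSE`.
#' @export
match_iupac <- function(pattern, window) {
  pc <- strsplit(toupper(pattern), "")[[1]]
  wc <- strsplit(toupper(window), "")[[1]]
  if (length(pc) != length(wc))
    stop("window length must equal pattern length")
  if (!all(pc %in% names(IUPAC_SETS)))
    stop("invalid IUPAC code(s): ",
         paste(setdiff(pc, names(IUPAC_SETS)), collapse = ", "))
  all(vapply(seq_along(pc),
             function(i) wc[i] != "N" && wc[i] %in% IUPAC_SETS[[pc[i]]],
             logical(1)))
}

# Sorted 1-based start positions of all (possibly overlapping) pattern
# occurrences. Vectorised over windows; N in the sequence never matches.
site_starts <- function(seq, enzyme) {
  seq <- canonical_sequence(seq)
  m <- nchar(enzyme$site)
  n <- nchar(seq)
  if (n < m) return(integer(0))
  pc <- strsplit(enzyme$site, "")[[1]]
  bases <- strsplit(seq, "")[[1]]
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    bj <- bases[seq.int(j, n - m + j)]
    ok <- ok & (bj != "N") & bj %in% IUPAC_SETS[[pc[j]]]
  }
  which(ok)
}

#' Locate restriction cut positions in a linear sequence
#'
#' Every occurrence of the enzyme's recognition site is reported, including
#' overlapping ones.  Cut positions are 0-based coordinates between bases:
#' a cut at position `p` falls between base `p` and base `p + 1`.
#'
#' @param seq Sequence string (A/C/G/T/N).
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted integer vector of cut positions (possibly empty).
#' @export
find_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  starts <- site_starts(seq, enzyme)
  sort(starts - 1L + enzyme$cut_offset)
}

#' Digest a linear sequence
#'
#' Complete digestion: all sites are cut simultaneously.  Fragment lengths
#' are differences between consecutive cut positions and always sum to the
#' sequence length.
#'
#' @inheritParams find_sites
#' @return An object of class `"digest_result"`: list with
#'   `fragment_lengths` (positive integers, descending) and `n_sites`.
#' @export
digest <- function(seq, enzyme) {
  seq <- canonical_sequence(seq)
  cuts <- find_sites(seq, enzyme)
  # cuts at 0 or at the full length split off zero-length fragments; drop
  cuts <- cuts[cuts > 0L & cuts < nchar(seq)]
  lens <- diff(c(0L, cuts, nchar(seq)))
  structure(list(fragment_lengths = sort(as.integer(lens), decreasing = TRUE),
                 n_sites = length(cuts)),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("digest: %d site(s); fragments [%s] bp\n", x$n_sites,
              paste(x$fragment_lengths, collapse = ", ")))
  invisible(x)
}

#' Reverse complement
#' @param seq Sequence string.
#' @return Reverse-complemented string (N maps to N).
#' @export
reverse_complement <- function(seq) {
  seq <- canonical_sequence(seq)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# all 1-based start positions of exact substring matches
substring_starts <- function(needle, haystack) {
  n <- nchar(haystack); m <- nchar(needle)
  if (n < m) return(integer(0))
  hits <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(needle, substr(haystack, from, n), fixed = TRUE)
    if (p < 0) break
    hits <- c(hits, from + as.integer(p) - 1L)
    from <- from + as.integer(p)
    if (from > n - m + 1L) break
  }
  hits
}

#' In-silico PCR: extract the amplicon defined by a primer pair
#'
#' Both primers are written 5'->3'.  The forward primer must match the
#' template exactly once; the reverse complement of the reverse primer must
#' match exactly once, downstream of the forward site.  Mismatch-tolerant
#' binding is deliberately unsupported.
#'
#' @param template Template sequence string.
#' @param forward,reverse Primer sequences (each >= 10 bases).
#' @return The amplicon substring, from the forward primer start to the end
#'   of the reverse-primer binding site (inclusive).
#' @export
find_amplicon <- function(template, forward, reverse) {
  template <- canonical_sequence(template)
  forward <- canonical_sequence(forward)
  reverse <- canonical_sequence(reverse)
  if (nchar(forward) < 10L || nchar(reverse) < 10L)
    stop("primers must be at least 10 bases long")
  fhits <- substring_starts(forward, template)
  rc <- reverse_complement(reverse)
  rhits <- substring_starts(rc, template)
  if (length(fhits) != 1L)
    stop("no amplicon: forward primer has ", length(fhits),
         " binding site(s), need exactly 1")
  rhits <- rhits[rhits >= fhits]                  # downstream only
  if (length(rhits) != 1L)
    stop("no amplicon: reverse primer has ", length(rhits),
         " downstream binding site(s), need exactly 1")
  rend <- rhits + nchar(rc) - 1L
  if (rend <= fhits + nchar(forward) - 1L)
    stop("no amplicon: reverse site does not extend past the forward primer")
  substr(template, fhits, rend)
}

#' Expected RFLP band patterns for a wild-type/mutant allele pair
#'
#' WT and MUT patterns are the complete digests of each allele; the HET
#' pattern is the union of the distinct band lengths of both alleles (a
#' heterozygote carries one copy of each).
#'
#' @param wt,mut Allele sequences.
#' @param enzyme A [restriction_enzyme()].
#' @return Named list `WT`/`HET`/`MUT` of sorted band-length vectors,
#'   class `"band_patterns"`.
#' @export
expected_band_patterns <- function(wt, mut, enzyme) {
  wt_b <- digest(wt, enzyme)$fragment_lengths
  mut_b <- digest(mut, enzyme)$fragment_lengths
  if (identical(wt_b, mut_b))
    stop("uninformative assay: wild-type and mutant digest patterns are identical")
  structure(list(WT = wt_b,
                 HET = sort(unique(c(wt_b, mut_b)), decreasing = TRUE),
                 MUT = mut_b),
            class = "band_patterns")
}

#' @export
print.band_patterns <- function(x, ...) {
  for (g in names(x))
    cat(sprintf("%-4s: %s bp\n", g, paste(x[[g]], collapse = " + ")))
  invisible(x)
}

# merge bands closer than tol into their mean (gel cannot resolve them)
merge_close_bands <- function(bands, tol) {
  bands <- sort(as.numeric(bands))
  if (length(bands) < 2L) return(bands)
  groups <- cumsum(c(1, diff(bands) > tol))
  as.numeric(tapply(bands, groups, mean))
}

#' Call a genotype from an observed band pattern
#'
#' Observed bands are compared against the expected WT/HET/MUT patterns
#' with a per-band size tolerance (gels resolve bands only approximately).
#' Bands closer together than the tolerance are merged before matching.
#' A pattern matches when observed and expected bands pair off one-to-one
#' within the tolerance.  No match, or more than one match, yields
#' `"UNKNOWN"` — a value, not an error.
#'
#' @param observed Numeric vector of observed band lengths (bp).
#' @param patterns [expected_band_patterns()] result.
#' @param tolerance Per-band matching tolerance in bp (default 5).
#' @return One of `"WT"`, `"HET"`, `"MUT"`, `"UNKNOWN"`.
#' @export
call_genotype <- function(observed, patterns, tolerance = 5) {
  if (length(observed) == 0L) return("UNKNOWN")
  observed <- suppressWarnings(as.numeric(observed))
  if (anyNA(observed) || any(observed <= 0)) return("UNKNOWN")
  obs <- merge_close_bands(observed, tolerance)
  hits <- names(patterns)[vapply(patterns, function(exp_b) {
    exp_b <- merge_close_bands(exp_b, tolerance)
    length(obs) == length(exp_b) &&
      all(abs(sort(obs) - sort(exp_b)) <= tolerance)
  }, logical(1))]
  if (length(hits) == 1L) hits else "UNKNOWN"
}

## ---- FASTA / band-table I/O -------------------------------------------

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(unlist(seqs), names(seqs))),
    path)
  invisible(path)
}

#' Read an observed gel-band table
#'
#' CSV with columns `sample_id` and `band_lengths`, the latter a
#' semicolon-separated list of integer band sizes.
#'
#' @param path CSV path.
#' @return Named list of numeric band vectors, one per sample.
#' @export
read_band_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character",
                                       band_lengths = "character"))
  bands <- lapply(df$band_lengths, function(s) {
    s <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    suppressWarnings(as.numeric(s[nzchar(s)]))
  })
  stats::setNames(bands, df$sample_id)
}
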