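# Synthetic multi-breed SNP-array data with recoverable ground truth.
#
# Breed allele frequencies drift from a shared ancestral frequency under
# the Balding-Nichols model: p_breed ~ Beta(p(1-c)/c, (1-p)(1-c)/c),
# where c is an F_ST-like drift parameter. Per individual, autozygous
# tracts are laid down as a Poisson process with exponentially distributed
# lengths of mean 100/(2g) Mb (segment age g generations, 1 cM per Mb);
# markers inside a tract are homozygous for a single haplotype draw.
# A selective sweep moves the focal breed's frequencies inside an interval
# to a configured final frequency with a linear 10-marker shoulder.

#' Build a simulation configuration
#'
#' Defaults emulate a 50K-array multi-breed goat panel: 29 autosomes,
#' ~1,500 markers per chromosome, six breeds of 13-29 animals — one
#' strongly drifted, inbred "exotic" breed (c = 0.2, autozygous fraction
#' 0.138) and five weakly drifted "indigenous" breeds (c = 0.05,
#' autozygous fractions 0.008-0.024), with one selective sweep in the
#' exotic breed and 1% missing calls.
#'
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given it.
#' @param breed_names Breed labels.
#' @param samples_per_breed Integer vector, same length as `breed_names`.
#' @param chrom_lengths_bp Named numeric vector of chromosome lengths.
#' @param markers_per_chrom Markers per chromosome (recycled).
#' @param drift Per-breed Balding-Nichols drift parameter `c` in (0, 1).
#' @param autozygosity_f Per-breed expected autozygous genome fraction in
#'   `[0, 1)`.
#' @param autozygosity_g Per-breed tract age in generations (mean tract
#'   length is `100 / (2 g)` Mb).
#' @param sweep `NULL` or a list with `breed`, `chromosome`, `start_bp`,
#'   `end_bp`, `final_freq`.
#' @param missing_rate i.i.d. missing-call probability.
#' @param maf_floor Ancestral frequencies are drawn uniformly on
#'   `[maf_floor, 1 - maf_floor]`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       breed_names = c("EXO", "IND1", "IND2", "IND3", "IND4", "IND5"),
                       samples_per_breed = c(13L, 15L, 29L, 29L, 29L, 29L),
                       chrom_lengths_bp = stats::setNames(
                         round(seq(155e6, 45e6, length.out = 29)),
                         as.character(1:29)),
                       markers_per_chrom = 1500L,
                       drift = c(0.2, 0.05, 0.05, 0.05, 0.05, 0.05),
                       autozygosity_f = c(0.138, 0.024, 0.013, 0.012, 0.012, 0.008),
                       autozygosity_g = c(10, 10, 25, 25, 25, 25),
                       sweep = list(breed = "EXO", chromosome = "1",
                                    start_bp = 60e6, end_bp = 65e6,
                                    final_freq = 0.95),
                       missing_rate = 0.01,
                       maf_floor = 0.1) {
  nb <- length(breed_names)
  cfg <- list(seed = as.integer(seed), breed_names = breed_names,
              samples_per_breed = rep_len(as.integer(samples_per_breed), nb),
              chrom_lengths_bp = chrom_lengths_bp,
              markers_per_chrom = rep_len(as.integer(markers_per_chrom),
                                          length(chrom_lengths_bp)),
              drift = rep_len(drift, nb),
              autozygosity_f = rep_len(autozygosity_f, nb),
              autozygosity_g = rep_len(autozygosity_g, nb),
              sweep = sweep, missing_rate = missing_rate,
              maf_floor = maf_floor)
  if (is.null(names(cfg$chrom_lengths_bp)))
    names(cfg$chrom_lengths_bp) <- as.character(seq_along(cfg$chrom_lengths_bp))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$drift <= 0 | cfg$drift >= 1))
    stopf("drift parameters must lie in (0, 1)")
  if (any(cfg$autozygosity_f < 0 | cfg$autozygosity_f >= 1))
    stopf("autozygous fractions must lie in [0, 1)")
  if (any(cfg$autozygosity_f > 0.8))
    stopf("autozygous fraction > 0.8 is infeasible for tract placement")
  if (any(cfg$autozygosity_g < 1))
    stopf("tract age must be >= 1 generation")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stopf("missing rate must lie in [0, 1)")
  if (cfg$maf_floor < 0 || cfg$maf_floor >= 0.5)
    stopf("maf_floor must lie in [0, 0.5)")
  if (!is.null(cfg$sweep)) {
    sw <- cfg$sweep
    if (!sw$breed %in% cfg$breed_names) stopf("sweep breed '%s' unknown", sw$breed)
    if (!as.character(sw$chromosome) %in% names(cfg$chrom_lengths_bp))
      stopf("sweep chromosome '%s' unknown", sw$chromosome)
    len <- cfg$chrom_lengths_bp[[as.character(sw$chromosome)]]
    if (sw$start_bp < 1 || sw$end_bp > len || sw$start_bp >= sw$end_bp)
      stopf("sweep interval outside chromosome bounds")
    if (sw$final_freq < 0 || sw$final_freq > 1)
      stopf("sweep final frequency must lie in [0, 1]")
  }
  invisible(cfg)
}

# Tract intensity calibration: a point x on a chromosome of length `len` is
# covered by a single uniform-start Exponential(mean_len) tract with
# probability (mean_len/len) * (1 - exp(-x/mean_len)); under a Poisson
# process of rate lambda the expected covered (union) fraction is
#   1 - (1/len) * int_0^len exp(-lambda * p_cover(x)) dx.
# Solve for lambda so that the *realized* coverage (after truncation at the
# chromosome end and merging of overlaps) has expectation f.
tract_lambda <- function(f, len, mean_len) {
  if (f <= 0) return(0)
  coverage <- function(lambda) {
    x <- seq(0, len, length.out = 512L)
    pc <- (mean_len / len) * (1 - exp(-x / mean_len))
    1 - mean(exp(-lambda * pc))
  }
  stats::uniroot(function(l) coverage(l) - f, c(1e-9, 1e6),
                 tol = 1e-9)$root
}

# merge possibly-overlapping tracts into their union
merge_tracts <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- out_e <- numeric(0)
  for (k in seq_along(start)[-1]) {
    if (start[k] <= me) me <- max(me, end[k])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[k]; me <- end[k] }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Simulate a multi-breed genotype dataset with ground truth
#'
#' Draws a marker map, ancestral and per-breed allele frequencies, per
#' individual autozygous tracts and genotype calls as described in
#' [sim_config()], and returns both the dataset and a truth table against
#' which every downstream estimate can be checked.
#'
#' @param config A [sim_config()].
#' @return List with elements `dataset` (a [genotype_dataset()]) and
#'   `truth`, a list with `tracts` (per-individual merged autozygous
#'   tracts), `autozygosity` (per-individual realized autozygous
#'   fraction), `breeds` (per-breed drift and inbreeding parameters),
#'   `sweep` and `frequencies` (ancestral and per-breed allele
#'   frequencies per marker).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chrs <- names(config$chrom_lengths_bp)
  nb <- length(config$breed_names)

  # --- marker map ------------------------------------------------------------
  map_list <- vector("list", length(chrs))
  for (ci in seq_along(chrs)) {
    m <- config$markers_per_chrom[ci]
    len <- config$chrom_lengths_bp[[ci]]
    pos <- sort(sample.int(len, m))
    map_list[[ci]] <- data.frame(
      marker_id = sprintf("snp_%s_%05d", chrs[ci], seq_len(m)),
      chromosome = chrs[ci], position_bp = pos,
      allele_a = "A", allele_b = "C", stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, map_list)
  m_tot <- nrow(map)

  # --- allele frequencies ----------------------------------------------------
  p_anc <- stats::runif(m_tot, config$maf_floor, 1 - config$maf_floor)
  p_breed <- matrix(NA_real_, m_tot, nb, dimnames = list(NULL, config$breed_names))
  for (b in seq_len(nb)) {
    c_b <- config$drift[b]
    p_breed[, b] <- stats::rbeta(m_tot, p_anc * (1 - c_b) / c_b,
                                 (1 - p_anc) * (1 - c_b) / c_b)
  }

  # --- sweep -----------------------------------------------------------------
  if (!is.null(config$sweep)) {
    sw <- config$sweep
    b <- match(sw$breed, config$breed_names)
    on_chr <- which(map$chromosome == as.character(sw$chromosome))
    core <- on_chr[map$position_bp[on_chr] >= sw$start_bp &
                   map$position_bp[on_chr] <= sw$end_bp]
    if (length(core)) {
      p_breed[core, b] <- sw$final_freq
      for (side in c(-1L, 1L)) {   # 10-marker linear shoulders
        edge <- if (side < 0) min(core) else max(core)
        for (k in 1:10) {
          at <- edge + side * k
          if (at < min(on_chr) || at > max(on_chr)) break
          w <- k / 11
          p_breed[at, b] <- w * p_breed[at, b] + (1 - w) * sw$final_freq
        }
      }
    }
  }

  # --- samples, tracts, genotypes -------------------------------------------
  genome_len <- sum(config$chrom_lengths_bp)
  samples <- data.frame(sample_id = character(0), breed = character(0))
  calls <- matrix(NA_integer_, sum(config$samples_per_breed), m_tot)
  tract_rows <- list()
  frac <- numeric(0)
  row_i <- 0L
  for (b in seq_len(nb)) {
    f <- config$autozygosity_f[b]
    g <- config$autozygosity_g[b]
    mean_len <- 100 / (2 * g) * 1e6          # bp
    lambdas <- vapply(config$chrom_lengths_bp, tract_lambda,
                      numeric(1), f = f, mean_len = mean_len)
    pb <- p_breed[, b]
    for (ind in seq_len(config$samples_per_breed[b])) {
      row_i <- row_i + 1L
      sid <- sprintf("%s_%02d", config$breed_names[b], ind)
      samples <- rbind(samples, data.frame(sample_id = sid,
                                           breed = config$breed_names[b]))
      geno <- stats::rbinom(m_tot, 2L, pb)
      covered <- 0
      for (ci in seq_along(chrs)) {
        len <- config$chrom_lengths_bp[[ci]]
        n_tr <- stats::rpois(1L, lambdas[[ci]])
        if (n_tr == 0L) next
        tr_s <- stats::runif(n_tr, 1, len)
        tr_e <- pmin(tr_s + stats::rexp(n_tr, rate = 1 / mean_len), len)
        mt <- merge_tracts(tr_s, tr_e)
        covered <- covered + sum(mt[, "end"] - mt[, "start"])
        on_chr <- which(map$chromosome == chrs[ci])
        for (t in seq_len(nrow(mt))) {
          inside <- on_chr[map$position_bp[on_chr] >= mt[t, "start"] &
                           map$position_bp[on_chr] <= mt[t, "end"]]
          if (length(inside))   # one haplotype draw per tract, doubled
            geno[inside] <- 2L * stats::rbinom(length(inside), 1L, pb[inside])
          tract_rows[[length(tract_rows) + 1L]] <- data.frame(
            sample_id = sid, chromosome = chrs[ci],
            start_bp = mt[t, "start"], end_bp = mt[t, "end"],
            length_bp = mt[t, "end"] - mt[t, "start"])
        }
      }
      frac <- c(frac, covered / genome_len)
      calls[row_i, ] <- geno
    }
  }

  if (config$missing_rate > 0) {
    mask <- stats::runif(length(calls)) < config$missing_rate
    calls[mask] <- NA_integer_
  }

  tracts <- if (length(tract_rows)) do.call(rbind, tract_rows) else
    data.frame(sample_id = character(), chromosome = character(),
               start_bp = numeric(), end_bp = numeric(), length_bp = numeric())
  truth <- list(
    tracts = tracts,
    autozygosity = data.frame(sample_id = samples$sample_id,
                              breed = samples$breed,
                              realized_fraction = frac),
    breeds = data.frame(breed = config$breed_names, drift = config$drift,
                        autozygosity_f = config$autozygosity_f,
                        autozygosity_g = config$autozygosity_g),
    sweep = config$sweep,
    frequencies = data.frame(marker_id = map$marker_id,
                             chromosome = map$chromosome,
                             position_bp = map$position_bp,
                             ancestral = p_anc, p_breed))
  list(dataset = genotype_dataset(calls, map, samples), truth = truth)
}
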