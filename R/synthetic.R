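#' Configuration of a synthetic accessibility/occupancy study
#'
#' Bundles every parameter of the generator: genome, accessible-region
#' geometry and fold-enrichments, Poisson tag background, the PWM set and
#' planted-site schedule, and the thermodynamic occupancy model
#' (`O = scale * A(x)^alpha * sum of Boltzmann site affinities`, reported
#' with multiplicative log-normal noise).
#'
#' @param seed master integer seed; every artifact derives its own stream
#'   from it.
#' @param genome a [genome_spec()] (default one 2-Mb chromosome).
#' @param bin_size track bin width (bp).
#' @param n_accessible number of accessible regions.
#' @param accessible_len_range length range (bp) of accessible regions.
#' @param min_region_gap minimum spacing (bp) between accessible regions
#'   (regions closer than the analysis window would behave as one
#'   domain).
#' @param strength_range fold-enrichment range of accessible regions over
#'   background (log-uniform).
#' @param lambda_bg expected tags per bin in closed chromatin.
#' @param n_factors number of transcription factors.
#' @param pwm_set optional list of [pwm()] (default: `n_factors` random
#'   informative width-`pwm_width` motifs).
#' @param pwm_width width of generated motifs.
#' @param planted_per_tier named counts of planted sites per factor in the
#'   accessible compartment, by affinity cohort (names in "-5".."-2").
#' @param planted_per_tier_closed same, for the closed compartment
#'   (defaults to `planted_per_tier`).
#' @param occupancy_alpha exponent on accessibility in the occupancy
#'   model.
#' @param occupancy_scale multiplicative scale of occupancy scores.
#' @param chip_noise_sigma sd of the log-normal multiplicative ChIP noise.
#' @param residual_affinity sequence-independent relative affinity added
#'   to every 1-kb window (widespread low-level binding).
#' @param site_affinity_p maximum match p-value for a scanned site to
#'   enter the occupancy substrate.
#' @param n_background_windows closed-chromatin control windows per
#'   factor.
#' @param fdr1_fraction,fdr25_fraction fractions of ranked ChIP peaks
#'   labelled with the 1% and 25% FDR tiers.
#' @param anchor_interior_bp when > 0, candidate ChIP windows inside
#'   accessible regions prefer anchor sites at least this far from the
#'   region edges, keeping the 1-kb window accessibility-homogeneous
#'   (used by model-identity validation configurations).
#' @param change_fraction fraction of accessible regions whose strength is
#'   modulated between stages.
#' @param modulation_range fold-change range (log-uniform) for modulated
#'   regions; `c(1, 1)` disables change.
#' @param stages names of the two developmental stages.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              genome = genome_spec("chrS", 2e6),
                              bin_size = 20,
                              n_accessible = 400,
                              accessible_len_range = c(500, 2000),
                              min_region_gap = 1000,
                              strength_range = c(2, 50),
                              lambda_bg = 2,
                              n_factors = 16,
                              pwm_set = NULL,
                              pwm_width = 8,
                              planted_per_tier = c("-5" = 40, "-4" = 40),
                              planted_per_tier_closed = planted_per_tier,
                              occupancy_alpha = 1,
                              occupancy_scale = 10,
                              chip_noise_sigma = 0.3,
                              residual_affinity = 0.003,
                              site_affinity_p = 10^-2.5,
                              n_background_windows = 600,
                              fdr1_fraction = 0.15,
                              fdr25_fraction = 0.85,
                              anchor_interior_bp = 0,
                              change_fraction = 0.5,
                              modulation_range = c(0.1, 10),
                              stages = c("stage1", "stage2")) {
  stopifnot(lambda_bg > 0, all(strength_range > 0), n_accessible >= 0,
            occupancy_scale > 0, chip_noise_sigma >= 0,
            fdr1_fraction > 0, fdr1_fraction <= 1,
            fdr25_fraction >= fdr1_fraction, fdr25_fraction <= 1,
            length(stages) == 2)
  cfg <- list(seed = as.integer(seed), genome = genome, bin_size = bin_size,
              n_accessible = n_accessible,
              accessible_len_range = accessible_len_range,
              min_region_gap = min_region_gap,
              strength_range = strength_range, lambda_bg = lambda_bg,
              n_factors = n_factors, pwm_set = pwm_set,
              pwm_width = pwm_width, planted_per_tier = planted_per_tier,
              planted_per_tier_closed = planted_per_tier_closed,
              occupancy_alpha = occupancy_alpha,
              occupancy_scale = occupancy_scale,
              chip_noise_sigma = chip_noise_sigma,
              residual_affinity = residual_affinity,
              site_affinity_p = site_affinity_p,
              n_background_windows = n_background_windows,
              fdr1_fraction = fdr1_fraction,
              fdr25_fraction = fdr25_fraction,
              anchor_interior_bp = anchor_interior_bp,
              change_fraction = change_fraction,
              modulation_range = modulation_range, stages = stages)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-artifact sub-seed below 2^31
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 99991) %% 2147483587)
}

#' Random informative PWMs
#'
#' Each column is a normalized Gamma draw with one strongly favoured base,
#' giving motifs of roughly 1-1.5 bits per position.
#'
#' @param n number of motifs.
#' @param width motif width.
#' @param seed integer seed (local).
#' @export
random_pwms <- function(n, width = 8, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      probs <- t(vapply(seq_len(width), function(j) {
        shape <- rep(0.35, 4)
        shape[sample.int(4, 1)] <- 8
        g <- stats::rgamma(4, shape)
        g / sum(g)
      }, numeric(4)))
      pwm(sprintf("TF%02d", k), probs)
    })
  })
}

# log10 p-value acceptance bands per affinity cohort, with a safety margin
# so that re-scanning reproduces the tier
tier_bands <- function(margin = 0.15) {
  list("-5" = c(-Inf, -4.5 - margin),
       "-4" = c(-4.5 + margin, -3.5 - margin),
       "-3" = c(-3.5 + margin, -2.5 - margin),
       "-2" = c(-2.5 + margin, log10(0.04) - margin))
}

# draw a site word from the tempered PWM (p^t * bg^(1-t)), landing in the
# requested cohort band; adapts t by bisection-style steps
sample_site_word <- function(pwm_obj, dist, tier, background,
                             max_tries = 500) {
  band <- tier_bands()[[tier]]
  smat <- logodds_matrix(pwm_obj, background)
  t <- switch(tier, "-5" = 1, "-4" = 0.8, "-3" = 0.55, "-2" = 0.3)
  probs0 <- reg_probs(pwm_obj, background)
  for (try in seq_len(max_tries)) {
    pt <- probs0^t * rep(background, each = pwm_obj$width)^(1 - t)
    pt <- pt / rowSums(pt)
    letters <- vapply(seq_len(pwm_obj$width), function(j)
      sample.int(4, 1, prob = pt[j, ]), 0L)
    s <- sum(smat[cbind(seq_len(pwm_obj$width), letters)])
    lp <- log10(score_pvalue(dist, s))
    if (lp >= band[1] && lp <= band[2])
      return(list(codes = letters, logodds = s, pvalue = 10^lp))
    if (lp < band[1]) t <- max(0, t - 0.05)   # too strong
    else t <- min(1, t + 0.05)                # too weak
  }
  stop("could not sample a tier ", tier, " site for ", pwm_obj$name)
}

#' Simulate a genome sequence with planted motif instances
#'
#' Background bases are i.i.d. from `background`; planted sites are draws
#' from (tempered) PWM column distributions placed on a uniformly chosen
#' strand, non-overlapping, inside the requested compartment. The truth
#' list records factor, position, strand, log-odds and match p-value.
#'
#' @param config a [simulation_config()].
#' @param regions accessible regions (interval data.frame) defining the
#'   accessible compartment; sites are planted inside (`accessible`) and
#'   outside (`closed`) per `config$planted_per_tier`.
#' @param background length-4 base frequencies (default uniform).
#' @return list with `sequence` (named character vector), `planted`
#'   (data.frame: factor, chrom, start, end, strand, logodds, pvalue,
#'   cohort, compartment), `pwms`, `dists` (per-factor score
#'   distributions).
#' @export
simulate_genome <- function(config, regions = empty_intervals(),
                            background = rep(0.25, 4)) {
  pwms <- config$pwm_set
  if (is.null(pwms))
    pwms <- random_pwms(config$n_factors, config$pwm_width,
                        seed = sub_seed(config$seed, 11))
  if (any(vapply(pwms, function(m) m$width, 0) < 4))
    stop("PWM widths must be >= 4")
  dists <- lapply(pwms, score_to_pvalue, background = background)
  names(dists) <- vapply(pwms, function(m) m$name, "")
  genome <- config$genome
  with_seed(sub_seed(config$seed, 23), {
    codes <- lapply(names(genome), function(ch)
      sample.int(4L, chrom_length(genome, ch), replace = TRUE,
                 prob = background))
    names(codes) <- names(genome)
    occupied <- lapply(names(genome), function(ch)
      logical(chrom_length(genome, ch)))
    names(occupied) <- names(genome)
    acc_by_chrom <- split(regions, regions$chrom)
    planted <- list()
    total_site_bp <- (sum(unlist(config$planted_per_tier)) +
                        sum(unlist(config$planted_per_tier_closed))) *
      config$n_factors * config$pwm_width
    if (total_site_bp > 0.5 * sum(unclass(genome)))
      stop("too many planted sites for the genome")
    for (f in seq_along(pwms)) {
      m <- pwms[[f]]
      for (compartment in c("accessible", "closed")) {
        tiers <- if (compartment == "accessible") config$planted_per_tier
          else config$planted_per_tier_closed
        for (tier in names(tiers)) {
          n_sites <- tiers[[tier]]
          placed <- 0
          guard <- 0
          while (placed < n_sites) {
            guard <- guard + 1
            if (guard > 200 * n_sites + 200)
              stop("could not place planted sites (", compartment, ")")
            ch <- sample(names(genome), 1)
            if (compartment == "accessible") {
              rg <- acc_by_chrom[[ch]]
              if (is.null(rg) || nrow(rg) == 0) next
              ri <- sample.int(nrow(rg), 1)
              if (rg$end[ri] - rg$start[ri] <= m$width) next
              pos <- rg$start[ri] +
                sample.int(rg$end[ri] - rg$start[ri] - m$width, 1)
            } else {
              pos <- sample.int(chrom_length(genome, ch) - m$width, 1)
              rg <- acc_by_chrom[[ch]]
              if (!is.null(rg) && nrow(rg) > 0 &&
                  any(pos + m$width > rg$start & pos < rg$end)) next
            }
            span <- (pos + 1):(pos + m$width)
            if (any(occupied[[ch]][span])) next
            site <- sample_site_word(m, dists[[m$name]], tier, background)
            strand <- sample(c("+", "-"), 1)
            w_codes <- site$codes
            if (strand == "-") w_codes <- rev(5L - w_codes)
            codes[[ch]][span] <- w_codes
            occupied[[ch]][span] <- TRUE
            planted[[length(planted) + 1L]] <- data.frame(
              factor = m$name, chrom = ch, start = pos,
              end = pos + m$width, strand = strand,
              logodds = site$logodds, pvalue = site$pvalue,
              cohort = as.integer(tier), compartment = compartment,
              stringsAsFactors = FALSE)
            placed <- placed + 1
          }
        }
      }
    }
    sequence <- vapply(codes, codes_to_seq, "")
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(factor = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0),
                 strand = character(0), logodds = numeric(0),
                 pvalue = numeric(0), cohort = integer(0),
                 compartment = character(0), stringsAsFactors = FALSE)
    list(sequence = sequence, planted = planted, pwms = pwms,
         dists = dists, background = background)
  })
}

#' Simulate replicate DNase tag tracks
#'
#' Bin counts are independent Poisson draws with mean `lambda_bg` outside
#' accessible regions and `lambda_bg * A_i` inside region i (bins
#' partially covered take the bp-weighted mean); replicates are i.i.d.
#' given the means.
#'
#' @param config a [simulation_config()].
#' @param regions accessible regions.
#' @param strengths per-region fold enrichment (A_i) for this stage.
#' @param n_replicates number of replicate tracks.
#' @param seed integer seed (local).
#' @return list of [tag_track()].
#' @export
simulate_dnase_tracks <- function(config, regions, strengths,
                                  n_replicates = 2, seed = config$seed) {
  genome <- config$genome
  bin <- config$bin_size
  means <- lapply(names(genome), function(ch) {
    nb <- ceiling(chrom_length(genome, ch) / bin)
    mu <- rep(config$lambda_bg, nb)
    idx <- which(regions$chrom == ch)
    for (i in idx) {
      b0 <- floor(regions$start[i] / bin) + 1
      b1 <- min(ceiling(regions$end[i] / bin), nb)
      bins <- b0:b1
      lo <- pmax((bins - 1) * bin, regions$start[i])
      hi <- pmin(bins * bin, regions$end[i])
      frac <- (hi - lo) / bin
      mu[bins] <- mu[bins] + config$lambda_bg * (strengths[i] - 1) * frac
    }
    mu
  })
  names(means) <- names(genome)
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      cts <- lapply(means, function(mu) as.numeric(stats::rpois(length(mu),
                                                                mu)))
      tag_track(genome, bin, cts)
    })
  })
}

# distance from each in-region position to the nearest edge of its
# containing region (NA when closed)
edge_distance <- function(chrom, position, regions) {
  out <- rep(NA_real_, length(position))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    rg <- which(regions$chrom == ch)
    if (!length(rg)) next
    o <- order(regions$start[rg])
    rg <- rg[o]
    j <- findInterval(position[idx], regions$start[rg])
    inside <- j >= 1 & position[idx] < regions$end[rg[pmax(j, 1)]]
    ii <- idx[inside]
    ri <- rg[j[inside]]
    out[ii] <- pmin(position[ii] - regions$start[ri],
                    regions$end[ri] - position[ii])
  }
  out
}

# fold enrichment A(x) at positions, given regions and strengths
strength_at <- function(chrom, position, regions, strengths) {
  out <- rep(1, length(position))
  if (nrow(regions) == 0) return(out)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    rg <- which(regions$chrom == ch)
    if (!length(rg)) next
    o <- order(regions$start[rg])
    rg <- rg[o]
    j <- findInterval(position[idx], regions$start[rg])
    inside <- j >= 1 & position[idx] < regions$end[rg[pmax(j, 1)]]
    out[idx[inside]] <- strengths[rg[j[inside]]]
  }
  out
}

#' Simulate ChIP scores under the widespread-binding occupancy model
#'
#' Candidate 1-kb windows are anchored at the highest-occupancy site of
#' each `tile_bp` tile of the site list; raw occupancy sums per-site
#' Boltzmann affinities weighted by the accessibility at each site and by
#' an exponential fragment-size kernel of the site's distance from the
#' window anchor (ChIP signal is localized to within a fragment length of
#' the bound site):
#' `O = scale * (A(anchor)^alpha * residual + sum over window sites of
#' A(site)^alpha * 2^(logodds - max logodds) * exp(-d / resolution))`.
#' The reported score multiplies O by `exp(N(0, sigma^2))`.
#' Closed-chromatin background windows are added, and peaks are ranked by
#' score to assign FDR tier labels.
#'
#' @param config a [simulation_config()].
#' @param regions accessible regions; `strengths` their per-region fold
#'   enrichments at this stage.
#' @param sites occupancy substrate for one factor: data.frame with
#'   `chrom`, `start`, `end`, `logodds` (typically planted sites plus all
#'   scanned genuine matches below `config$site_affinity_p`).
#' @param pwm_obj the factor's [pwm()].
#' @param strengths per-region accessibility strengths.
#' @param anchor_strengths strengths used only to pick window anchor
#'   sites; defaults to `strengths`. Passing the first stage's strengths
#'   for every stage keeps the candidate window set fixed across stages
#'   (scores are still computed from `strengths`).
#' @param background length-4 frequencies used for the log-odds ceiling.
#' @param seed integer seed (local).
#' @return data.frame of ChIP peaks: `factor`, `chrom`, `peak_position`,
#'   `start`, `end`, `score`, `fdr_tier`, `occupancy` (noise-free),
#'   `accessibility`.
#' @export
simulate_chip_scores <- function(config, regions, sites, pwm_obj,
                                 strengths, anchor_strengths = strengths,
                                 background = rep(0.25, 4),
                                 seed = config$seed, tile_bp = 250,
                                 resolution_bp = 250) {
  genome <- config$genome
  empty <- data.frame(factor = character(0), chrom = character(0),
                      peak_position = numeric(0), start = numeric(0),
                      end = numeric(0), score = numeric(0),
                      fdr_tier = character(0), occupancy = numeric(0),
                      accessibility = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sites) == 0) return(empty)
  smax <- sum(apply(logodds_matrix(pwm_obj, background), 1, max))
  mid <- if ("mid" %in% names(sites)) sites$mid else
    floor((sites$start + sites$end) / 2)
  relaff <- 2^(sites$logodds - smax)
  A_site <- strength_at(sites$chrom, mid, regions, strengths)
  occ_w <- A_site^config$occupancy_alpha * relaff
  A_anchor <- strength_at(sites$chrom, mid, regions, anchor_strengths)
  anchor_w <- A_anchor^config$occupancy_alpha * relaff
  anchor_ok <- rep(TRUE, length(mid))
  buf <- config$anchor_interior_bp
  if (!is.null(buf) && buf > 0 && nrow(regions) > 0) {
    edge <- edge_distance(sites$chrom, mid, regions)
    anchor_ok <- is.na(edge) | edge >= buf
  }
  wins <- list()
  for (ch in unique(sites$chrom)) {
    sel <- sites$chrom == ch
    pos <- mid[sel]; w <- occ_w[sel]; aw <- anchor_w[sel]
    aok <- anchor_ok[sel]
    o <- order(pos)
    pos <- pos[o]; w <- w[o]; aw <- aw[o]; aok <- aok[o]
    tile <- floor(pos / tile_bp)
    best <- tapply(seq_along(pos), tile, function(ii) {
      el <- ii[aok[ii]]
      if (length(el)) el[which.max(aw[el])] else ii[which.max(aw[ii])]
    })
    peak <- pos[as.integer(best)]
    lo <- findInterval(peak - 500 - 0.5, pos) + 1L
    hi <- findInterval(peak + 499 + 0.5, pos)
    nsite <- hi - lo + 1L
    site_idx <- sequence(nsite) + rep(lo - 1L, nsite)
    win_id <- rep(seq_along(peak), nsite)
    kern <- exp(-abs(pos[site_idx] - rep(peak, nsite)) / resolution_bp)
    occ <- numeric(length(peak))
    agg <- rowsum(w[site_idx] * kern, win_id)
    occ[as.integer(rownames(agg))] <- agg
    wins[[ch]] <- data.frame(chrom = ch, peak_position = peak,
                             occ_sum = occ, stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, wins)
  with_seed(seed, {
    # closed-background control windows
    nbg <- config$n_background_windows
    if (nbg > 0) {
      ch_bg <- sample(names(genome), nbg, replace = TRUE,
                      prob = unclass(genome) / sum(unclass(genome)))
      pos_bg <- vapply(ch_bg, function(ch)
        sample.int(chrom_length(genome, ch) - 1000, 1) + 500, 0)
      far <- rep(TRUE, nbg)
      for (ch in unique(ch_bg)) {
        i <- which(ch_bg == ch)
        pk <- win$peak_position[win$chrom == ch]
        if (length(pk))
          far[i] <- vapply(pos_bg[i], function(p) all(abs(pk - p) > 1000),
                           TRUE)
      }
      if (any(far))
        win <- rbind(win, data.frame(chrom = ch_bg[far],
                                     peak_position = pos_bg[far],
                                     occ_sum = 0, stringsAsFactors = FALSE))
    }
    A <- strength_at(win$chrom, win$peak_position, regions, strengths)
    O <- config$occupancy_scale *
      (win$occ_sum +
         A^config$occupancy_alpha * config$residual_affinity)
    noise <- if (config$chip_noise_sigma > 0)
      exp(stats::rnorm(nrow(win), 0, config$chip_noise_sigma)) else 1
    score <- O * noise
    out <- data.frame(factor = pwm_obj$name, chrom = win$chrom,
                      peak_position = win$peak_position,
                      start = pmax(0, win$peak_position - 500),
                      end = pmin(chrom_length(genome, win$chrom),
                                 win$peak_position + 500),
                      score = score, fdr_tier = "none",
                      occupancy = O, accessibility = A,
                      stringsAsFactors = FALSE)
    rk <- rank(-out$score, ties.method = "first")
    out$fdr_tier[rk <= config$fdr25_fraction * nrow(out)] <- "25%"
    out$fdr_tier[rk <= config$fdr1_fraction * nrow(out)] <- "1%"
    out <- out[order(-out$score), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Peaks at or above an FDR tier
#'
#' @param chip_peaks ChIP peak data.frame with an `fdr_tier` column.
#' @param tier `"1%"` (strictest set) or `"25%"` (includes the 1% set).
#' @export
chip_fdr_subset <- function(chip_peaks, tier = c("25%", "1%")) {
  tier <- match.arg(tier)
  keep <- if (tier == "1%") chip_peaks$fdr_tier == "1%" else
    chip_peaks$fdr_tier %in% c("1%", "25%")
  chip_peaks[keep, , drop = FALSE]
}

#' Generate a complete two-stage synthetic study
#'
#' Draws accessible regions with per-stage fold enrichments (stage 2
#' modulated per `config`), a genome with planted motif instances,
#' two replicate DNase tracks per stage, and per-factor ChIP peak lists
#' under the occupancy model. The occupancy substrate per factor is the
#' union of planted sites and all scanned genuine matches with
#' `p < config$site_affinity_p`, so low-level widespread binding arises at
#' background recognition sites as well.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_study`: list with `config`,
#'   `regions` (with `strength_stage1`, `strength_stage2`, `modulation`),
#'   `sequence`, `planted`, `sites`, `pwms`, `dists`, `tracks`
#'   (stage -> list of replicate tracks), `chip` (stage -> data.frame of
#'   all factors' peaks), `background`.
#' @export
simulate_study <- function(config = simulation_config()) {
  genome <- config$genome
  regions <- with_seed(sub_seed(config$seed, 5), {
    chrom_w <- unclass(genome) / sum(unclass(genome))
    per_chrom <- round(config$n_accessible * chrom_w)
    rs <- list()
    for (ch in names(genome)) {
      n <- per_chrom[[ch]]
      if (n == 0) next
      len <- chrom_length(genome, ch)
      slot <- floor(len / n)
      gap <- config$min_region_gap
      width <- round(stats::runif(n, config$accessible_len_range[1],
                                  config$accessible_len_range[2]))
      width <- pmin(width, slot - gap - config$bin_size)
      start <- (seq_len(n) - 1) * slot + ceiling(gap / 2) +
        floor(stats::runif(n) * (slot - gap - width))
      rs[[ch]] <- data.frame(chrom = ch, start = start,
                             end = start + width, stringsAsFactors = FALSE)
    }
    rs <- do.call(rbind, rs)
    rs$name <- sprintf("truth_%d", seq_len(nrow(rs)))
    lsr <- log10(config$strength_range)
    rs$strength_stage1 <- 10^stats::runif(nrow(rs), lsr[1], lsr[2])
    mod <- rep(1, nrow(rs))
    chg <- stats::runif(nrow(rs)) < config$change_fraction
    lmr <- log10(config$modulation_range)
    mod[chg] <- 10^stats::runif(sum(chg), lmr[1], lmr[2])
    rs$modulation <- mod
    rs$strength_stage2 <- rs$strength_stage1 * mod
    class(rs) <- c("interval_df", "data.frame")
    rs
  })
  gen <- simulate_genome(config, regions)
  # occupancy substrate: scanned genuine matches (planted sites are in the
  # sequence, so the scan recovers them too)
  codes_list <- lapply(gen$sequence, seq_to_codes)
  sites <- lapply(gen$pwms, function(m) {
    mt <- scan_match_mid_cohort(gen$sequence, m, gen$dists[[m$name]],
                                p_max = config$site_affinity_p,
                                codes_list = codes_list)
    mt
  })
  names(sites) <- names(gen$dists)
  tracks <- list()
  chip <- list()
  for (si in 1:2) {
    stage <- config$stages[si]
    strengths <- regions[[paste0("strength_stage", si)]]
    tracks[[stage]] <- simulate_dnase_tracks(
      config, regions, strengths, n_replicates = 2,
      seed = sub_seed(config$seed, 31 + si))
    chip[[stage]] <- do.call(rbind, lapply(seq_along(gen$pwms), function(f)
      simulate_chip_scores(config, regions, sites[[f]], gen$pwms[[f]],
                           strengths,
                           anchor_strengths = regions$strength_stage1,
                           background = gen$background,
                           seed = sub_seed(config$seed, 57 + 100 * si + f))))
    rownames(chip[[stage]]) <- NULL
  }
  structure(list(config = config, regions = regions,
                 sequence = gen$sequence, planted = gen$planted,
                 sites = sites, pwms = gen$pwms, dists = gen$dists,
                 tracks = tracks, chip = chip,
                 background = gen$background),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", sum(unclass(x$config$genome)), "bp genome,",
      nrow(x$regions), "accessible regions,", length(x$pwms), "factors,",
      "stages:", paste(x$config$stages, collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits FASTA (genome), bedGraph (per stage/replicate tracks), BED5
#' (truth regions, planted sites, per-stage ChIP peaks), MEME-minimal
#' (PWM set) and a JSON echo of the scalar configuration.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::DNAStringSet(study$sequence)
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fa"))
  write_chrom_sizes(study$config$genome, file.path(dir, "genome.chrom.sizes"))
  for (stage in names(study$tracks))
    for (r in seq_along(study$tracks[[stage]]))
      write_track_as_bedgraph(study$tracks[[stage]][[r]],
                              file.path(dir, sprintf("dnase_%s_rep%d.bedGraph",
                                                     stage, r)))
  truth <- study$regions
  truth$score <- truth$strength_stage1
  write_bed(truth, file.path(dir, "truth_regions.bed"))
  if (nrow(study$planted)) {
    pl <- intervals(study$planted$chrom, study$planted$start,
                    study$planted$end, name = study$planted$factor,
                    score = study$planted$logodds)
    write_bed(pl, file.path(dir, "planted_sites.bed"))
  }
  for (stage in names(study$chip)) {
    cp <- study$chip[[stage]]
    write_bed(intervals(cp$chrom, cp$start, cp$end, name = cp$factor,
                        score = cp$score),
              file.path(dir, sprintf("chip_%s.bed", stage)))
  }
  write_meme_minimal(study$pwms, file.path(dir, "motifs.meme"))
  cfg <- study$config
  scalars <- cfg[!vapply(cfg, is.object, TRUE) &
                   !names(cfg) %in% c("pwm_set", "genome")]
  jsonlite::write_json(scalars, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
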