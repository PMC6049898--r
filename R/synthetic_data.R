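# Fully labeled synthetic experiments: intensity pairs with known
# cooperative/non-cooperative membership, wild-type and knockout replicate
# peak files, a single-contig genome with planted motif sites, and a truth
# table. The generator realizes exactly the statistical structure the
# detector assumes — a two-component product-marginal intensity mixture in
# which the cooperative component binds the target more weakly — plus the
# knockout design used for validation: cooperative target peaks disappear
# (or are attenuated) after partner knockout.

#' Simulation configuration
#'
#' Defaults mirror the intensity structure the detector is built around:
#' log-normal marginals with the cooperative component markedly weaker on
#' the target axis (log-location 1.0 vs 2.5) and nearly identical on the
#' partner axis (2.0 vs 2.1), and a cooperative fraction of 0.4.
#'
#' @param n_pairs number of doubly bound regions.
#' @param weight cooperative fraction w in `[0, 1]`.
#' @param family marginal family for intensities.
#' @param coop_target,coop_partner,noncoop_target,noncoop_partner
#'   `c(location, scale)` for each marginal.
#' @param p_loss probability that a cooperative target peak is lost entirely
#'   in the knockout (decided once per peak, shared by all knockout
#'   replicates — the loss is a property of the genotype).
#' @param attenuation intensity multiplier in `(0, 1]` for cooperative target
#'   peaks that survive the knockout (the "reduced in intensity" class).
#' @param replicate_log_sd log-scale sd of multiplicative replicate noise.
#' @param n_wt_replicates,n_ko_replicates replicate counts.
#' @param genome_length single-contig genome length in bp.
#' @param peak_meanlog,peak_sdlog log-normal peak-length distribution
#'   (lengths are rounded and floored at 50 bp).
#' @param motif_rate fraction of directly bound peaks that carry a planted
#'   motif site at the summit.
#' @param pwm optional [pwm()] used for motif planting (default: a sharp
#'   8-bp site).
#' @param background genome letter frequencies (A, C, G, T).
#' @param seed integer seed.
#' @return list with class `sim_config`.
#' @export
sim_config <- function(n_pairs = 4000L,
                       weight = 0.4,
                       family = "lognormal",
                       coop_target = c(1.0, 0.5),
                       coop_partner = c(2.0, 0.6),
                       noncoop_target = c(2.5, 0.5),
                       noncoop_partner = c(2.1, 0.6),
                       p_loss = 0.8,
                       attenuation = 0.5,
                       replicate_log_sd = 0.1,
                       n_wt_replicates = 2L,
                       n_ko_replicates = 2L,
                       genome_length = 2e6,
                       peak_meanlog = log(200),
                       peak_sdlog = 0.25,
                       motif_rate = 0.8,
                       pwm = NULL,
                       background = c(0.3, 0.2, 0.2, 0.3),
                       seed = 1L) {
  family <- match.arg(family, .families)
  stopifnot(weight >= 0, weight <= 1, p_loss >= 0, p_loss <= 1,
            attenuation > 0, attenuation <= 1,
            coop_target[2] > 0, coop_partner[2] > 0,
            noncoop_target[2] > 0, noncoop_partner[2] > 0)
  mk <- function(v) marginal_params(family, v[1], v[2])
  cfg <- list(
    n_pairs = as.integer(n_pairs), weight = weight, family = family,
    coop_target = mk(coop_target), coop_partner = mk(coop_partner),
    noncoop_target = mk(noncoop_target), noncoop_partner = mk(noncoop_partner),
    p_loss = p_loss, attenuation = attenuation,
    replicate_log_sd = replicate_log_sd,
    n_wt_replicates = as.integer(n_wt_replicates),
    n_ko_replicates = as.integer(n_ko_replicates),
    genome_length = as.integer(genome_length),
    peak_meanlog = peak_meanlog, peak_sdlog = peak_sdlog,
    motif_rate = motif_rate,
    pwm = if (is.null(pwm)) default_sim_pwm(background) else pwm,
    background = background / sum(background),
    seed = as.integer(seed)
  )
  if (axis_mean(cfg$coop_target) >= axis_mean(cfg$noncoop_target)) {
    stop("config must place the cooperative target location below the ",
         "non-cooperative one (cooperatively bound targets bind weakly)")
  }
  structure(cfg, class = "sim_config")
}

# A sharp 8-bp palindromic-ish site: informative enough that planted sites
# separate cleanly from background hits.
#' @keywords internal
default_sim_pwm <- function(background = rep(0.25, 4)) {
  consensus <- c("T", "G", "A", "C", "G", "T", "C", "A")
  counts <- sapply(consensus, function(b) {
    v <- rep(2, 4)
    v[match(b, .dna_alphabet)] <- 94
    v
  })
  pwm_from_counts(counts, background / sum(background))
}

#' @keywords internal
draw_marginal <- function(n, params) {
  switch(params$family,
    lognormal = stats::rlnorm(n, params$location, params$scale),
    gamma = stats::rgamma(n, shape = params$location, scale = params$scale),
    gaussian = stats::rnorm(n, params$location, params$scale)
  )
}

#' Simulate labeled intensity pairs
#'
#' Each pair is cooperative with probability `weight`; x and y are drawn
#' independently from the component's target/partner marginals.
#'
#' @param config a [sim_config()].
#' @return list: `pairs` (data frame with `x`, `y`) and `cooperative`
#'   (logical truth labels).
#' @export
simulate_intensity_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_pairs
    coop <- stats::runif(n) < config$weight
    x <- numeric(n); y <- numeric(n)
    x[coop] <- draw_marginal(sum(coop), config$coop_target)
    y[coop] <- draw_marginal(sum(coop), config$coop_partner)
    x[!coop] <- draw_marginal(sum(!coop), config$noncoop_target)
    y[!coop] <- draw_marginal(sum(!coop), config$noncoop_partner)
    list(pairs = data.frame(x = x, y = y), cooperative = coop)
  })
}

# Place n non-overlapping intervals of the given lengths on [0, genome_len).
#' @keywords internal
place_nonoverlapping <- function(n, lengths, genome_len, max_rounds = 50L) {
  starts <- integer(0); ends <- integer(0)
  lengths <- rep_len(as.integer(lengths), n)
  if (sum(lengths + 1) > genome_len) {
    stop("genome too small to place ", n, " non-overlapping peaks")
  }
  remaining <- lengths
  for (round in seq_len(max_rounds)) {
    if (length(remaining) == 0L) break
    cand_start <- as.integer(floor(stats::runif(length(remaining)) *
                                     (genome_len - remaining)))
    cand_end <- cand_start + remaining
    # drop candidates that touch an already accepted interval
    ok <- rep(TRUE, length(remaining))
    if (length(starts)) {
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(cand_start + 1L, cand_end),
        IRanges::IRanges(starts + 1L, ends))
      ok[unique(S4Vectors::queryHits(hits))] <- FALSE
    }
    # greedy left-to-right de-overlap within the batch
    keep <- logical(length(remaining))
    last_end <- -1L
    for (k in which(ok)[order(cand_start[ok])]) {
      if (cand_start[k] >= last_end) {
        keep[k] <- TRUE
        last_end <- cand_end[k]
      }
    }
    starts <- c(starts, cand_start[keep])
    ends <- c(ends, cand_end[keep])
    remaining <- remaining[!keep]
  }
  if (length(remaining) > 0L) {
    stop("could not place ", n, " non-overlapping peaks in ", genome_len,
         " bp after ", max_rounds, " rounds")
  }
  ord <- order(starts)
  list(start = starts[ord], end = ends[ord])
}

#' Simulate a full knockout-validation experiment
#'
#' Generates a single-contig genome with i.i.d. background letters; places
#' non-overlapping target peaks and one partner peak overlapping each; draws
#' intensity pairs from the configured mixture; produces wild-type target
#' replicates (multiplicative log-normal replicate noise), a partner peak
#' set, and knockout replicates in which each cooperative target peak is
#' lost with probability `p_loss` (a per-peak genotype decision shared by
#' replicates) and otherwise attenuated; plants a motif site at the summit
#' of directly bound peaks at rate `motif_rate`; and records every generated
#' label in a truth table.
#'
#' Partner peak placement (offset and length) is independent of the
#' cooperative label, so summit distance carries no label information — by
#' design, to test that distance-based detection has no signal here.
#'
#' @param config a [sim_config()].
#' @return list with elements `wt_target` (list of [peak_table()]s),
#'   `partner` ([peak_table()]), `ko_target` (list of [peak_table()]s),
#'   `genome` (named `Biostrings::DNAStringSet`), `truth` (data frame:
#'   region, coordinates, cooperative flag, lost flag, motif flag), and
#'   `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_pairs
    glen <- config$genome_length
    # peak geometry
    t_len <- pmax(50L, as.integer(round(stats::rlnorm(n, config$peak_meanlog,
                                                      config$peak_sdlog))))
    pos <- place_nonoverlapping(n, t_len, glen)
    t_start <- pos$start; t_end <- pos$end
    t_len <- t_end - t_start
    # summits uniform in the central half of each peak
    t_summit <- t_start + as.integer(floor(t_len / 4 +
                                             stats::runif(n) * (t_len / 2)))
    # partner peaks: length from the same distribution, shifted so the
    # overlap is >= 1 bp; the offset is drawn independently of the label
    p_len <- pmax(50L, as.integer(round(stats::rlnorm(n, config$peak_meanlog,
                                                      config$peak_sdlog))))
    shift <- as.integer(floor(stats::runif(n, -0.8, 0.8) * pmin(t_len, p_len)))
    p_start <- pmax(0L, pmin(t_start + shift, glen - p_len))
    p_end <- p_start + p_len
    p_summit <- p_start + as.integer(floor(p_len / 4 +
                                             stats::runif(n) * (p_len / 2)))
    # intensities and labels
    coop <- stats::runif(n) < config$weight
    x <- numeric(n); y <- numeric(n)
    x[coop] <- draw_marginal(sum(coop), config$coop_target)
    y[coop] <- draw_marginal(sum(coop), config$coop_partner)
    x[!coop] <- draw_marginal(sum(!coop), config$noncoop_target)
    y[!coop] <- draw_marginal(sum(!coop), config$noncoop_partner)
    x <- pmax(x, 1e-3); y <- pmax(y, 1e-3)
    # knockout genotype: which cooperative peaks are lost
    lost <- coop & stats::runif(n) < config$p_loss
    mk_peaks <- function(start, end, summit, signal, prefix) {
      peak_table(chrom = "chrSim", start = start, end = end,
                 name = paste0(prefix, seq_along(start)),
                 score = pmin(1000L, as.integer(round(10 * signal))),
                 signal = signal, summit_offset = as.integer(summit - start))
    }
    jitter_rep <- function(v) v * exp(stats::rnorm(length(v), 0,
                                                   config$replicate_log_sd))
    wt_target <- lapply(seq_len(config$n_wt_replicates), function(r) {
      mk_peaks(t_start, t_end, t_summit, jitter_rep(x), sprintf("wt%d_t", r))
    })
    partner <- mk_peaks(p_start, p_end, p_summit, y, "p")
    ko_target <- lapply(seq_len(config$n_ko_replicates), function(r) {
      keep <- !lost
      sig <- x[keep] * ifelse(coop[keep], config$attenuation, 1)
      mk_peaks(t_start[keep], t_end[keep], t_summit[keep],
               jitter_rep(sig), sprintf("ko%d_t", r))
    })
    # genome with planted motif sites at target summits
    letters_ <- sample(.dna_alphabet, glen, replace = TRUE,
                       prob = config$background)
    motif <- stats::runif(n) < config$motif_rate
    w <- config$pwm$width
    probs <- 2^config$pwm$scores * config$pwm$background  # back to frequencies
    probs <- sweep(probs, 2, colSums(probs), "/")
    for (i in which(motif)) {
      at <- min(max(t_summit[i] - w %/% 2, 0L), glen - w)
      site <- vapply(seq_len(w), function(j) {
        sample(.dna_alphabet, 1L, prob = probs[, j])
      }, character(1))
      letters_[(at + 1L):(at + w)] <- site
    }
    genome <- Biostrings::DNAStringSet(paste(letters_, collapse = ""))
    names(genome) <- "chrSim"
    truth <- data.frame(
      region = paste0("r", seq_len(n)),
      chrom = "chrSim", start = t_start, end = t_end,
      x = x, y = y,
      cooperative = coop, lost = lost, motif = motif,
      summit_distance = abs(t_summit - p_summit),
      stringsAsFactors = FALSE
    )
    list(wt_target = wt_target, partner = partner, ko_target = ko_target,
         genome = genome, truth = truth, config = config)
  })
}

#' Write a simulated experiment to disk
#'
#' Emits narrowPeak files for every replicate, the genome as FASTA, and the
#' truth table as TSV — all formats the reading side of the package accepts.
#'
#' @param experiment a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (r in seq_along(experiment$wt_target)) {
    p <- file.path(dir, sprintf("wt_target_rep%d.narrowPeak", r))
    write_narrowpeak(experiment$wt_target[[r]], p)
    paths[sprintf("wt_target_rep%d", r)] <- p
  }
  for (r in seq_along(experiment$ko_target)) {
    p <- file.path(dir, sprintf("ko_target_rep%d.narrowPeak", r))
    write_narrowpeak(experiment$ko_target[[r]], p)
    paths[sprintf("ko_target_rep%d", r)] <- p
  }
  paths["partner"] <- file.path(dir, "partner.narrowPeak")
  write_narrowpeak(experiment$partner, paths["partner"])
  paths["genome"] <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(experiment$genome, paths["genome"])
  paths["truth"] <- file.path(dir, "truth.tsv")
  utils::write.table(experiment$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
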