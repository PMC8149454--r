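#' @title Synthetic data with known ground truth
#' @description Generators for every input the pipeline consumes — genome
#'   and repeat annotation, replicate peak calls with planted motif sites,
#'   organ-by-gene expression with a planted enriched subset, dual-luciferase
#'   tables under null/additive/synergistic effect models, and ChIP-qPCR Ct
#'   tables with a known true fold enrichment. Every generator is a pure
#'   function of its configuration and seed and returns a truth table
#'   sufficient to score the downstream stage.
#' @name synthetic_data
NULL

#' Simulate a genome with repeat annotation
#'
#' I.i.d. nucleotide sequence at a given GC content, with repeat intervals
#' placed uniformly at a configurable density.
#'
#' @param n_chrom number of chromosomes.
#' @param length length of each chromosome (>= 1000 nt).
#' @param gc GC content in (0, 1).
#' @param repeat_density target fraction of each chromosome covered by
#'   repeat intervals (0 disables repeats).
#' @param repeat_length length of each repeat interval.
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @return list: `genome` (named `DNAStringSet`), `repeats` (tibble
#'   `chrom`, `start`, `end`, 0-based half-open).
#' @export
gen_genome <- function(n_chrom = 2, length = 50000, gc = 0.35,
                       repeat_density = 0.05, repeat_length = 200,
                       seed = NULL) {
  if (length < 1000) abort("`length` must be at least 1000.")
  check_probability(gc, "gc", allow_one = FALSE)
  check_probability(repeat_density, "repeat_density", allow_zero = TRUE,
                    allow_one = FALSE)
  freqs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_chrom), function(i) {
      paste(sample(DNA_BASES4, length, replace = TRUE, prob = freqs),
            collapse = "")
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- paste0("chr", seq_len(n_chrom))
    n_rep <- round(repeat_density * length / repeat_length)
    repeats <- if (n_rep > 0) {
      list_rbind(map(names(genome), function(chr) {
        starts <- sort(sample.int(length - repeat_length, n_rep))
        tibble(chrom = chr, start = starts, end = starts + repeat_length)
      }))
    } else {
      tibble(chrom = character(), start = integer(), end = integer())
    }
    list(genome = genome, repeats = repeats)
  })
}

# sample one site from the PWM's own probability distribution; with a
# threshold, rejection-sample until the site scores at or above it
.sample_site <- function(pwm, threshold = NULL, background = NULL,
                         max_tries = 1000) {
  draw <- function() {
    paste(apply(pwm$matrix, 1, function(p) sample(DNA_BASES4, 1, prob = p)),
          collapse = "")
  }
  if (is.null(threshold)) return(draw())
  cut <- if (inherits(threshold, "scan_threshold")) threshold$threshold else threshold
  best <- NULL; best_score <- -Inf
  for (i in seq_len(max_tries)) {
    s <- draw()
    sc <- score_window(pwm, s, background)
    if (sc >= cut) return(s)
    if (sc > best_score) { best <- s; best_score <- sc }
  }
  warn("could not sample a site above threshold; returning the best found.")
  best
}

#' Simulate replicate peak calls with planted motif sites
#'
#' Places non-overlapping base peaks uniformly on the genome; a fraction of
#' them receive one motif site sampled from the PWM's own probability
#' distribution (rejection-sampled above `threshold` when one is given),
#' written into the genome sequence at the peak centre. Each replicate
#' perturbs peak boundaries by up to `jitter` bp and drops peaks
#' independently with probability `dropout`.
#'
#' @param genome named `DNAStringSet`, e.g. from [gen_genome()].
#' @param pwm motif to plant.
#' @param n_peaks number of base peaks (spread across chromosomes).
#' @param peak_length base peak length in bp.
#' @param planted_fraction fraction of peaks receiving a site.
#' @param jitter maximum boundary perturbation per replicate (bp).
#' @param dropout per-replicate probability of losing a peak.
#' @param threshold optional [calibrate_threshold()] result (or bits) the
#'   planted sites must score at or above.
#' @param background frequencies used when scoring candidate sites.
#' @param seed integer seed.
#' @return list: `rep1`, `rep2` (peak tibbles), `base_peaks`, `truth`
#'   (tibble `peak_id`, `chrom`, `start`, `end`, `planted`, `site_start`,
#'   `site_seq`, `site_score`), and `genome` (the sequence with sites
#'   written in).
#' @export
gen_peaks_with_motifs <- function(genome, pwm, n_peaks = 100,
                                  peak_length = 300, planted_fraction = 0.5,
                                  jitter = 20, dropout = 0.1,
                                  threshold = NULL, background = NULL,
                                  seed = NULL) {
  stopifnot(inherits(genome, "DNAStringSet"), inherits(pwm, "pwm"))
  check_probability(planted_fraction, "planted_fraction", allow_zero = TRUE)
  check_probability(dropout, "dropout", allow_zero = TRUE, allow_one = FALSE)
  L <- nrow(pwm$matrix)
  if (peak_length < L + 2 * jitter + 2) abort("`peak_length` too short for the motif and jitter.")
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  with_seed(seed, {
    # spread peaks over chromosomes proportionally to length, pack on a
    # slot grid so they never overlap
    share <- chrom_len / sum(chrom_len)
    n_per <- stats::setNames(as.integer(round(n_peaks * share)), names(genome))
    n_per[1] <- n_per[1] + n_peaks - sum(n_per)
    slot <- peak_length + 2 * jitter + 10
    base <- list_rbind(map(names(genome), function(chr) {
      n_slots <- (chrom_len[[chr]] - 2 * jitter) %/% slot
      if (n_per[[chr]] > n_slots) {
        abort(paste0("cannot pack ", n_per[[chr]], " peaks of ", peak_length,
                     " bp on ", chr, "."))
      }
      if (n_per[[chr]] == 0) return(NULL)
      starts <- jitter + (sort(sample.int(n_slots, n_per[[chr]])) - 1L) * slot
      tibble(chrom = chr, start = as.integer(starts),
             end = as.integer(starts + peak_length))
    }))
    base <- mutate(base,
      peak_id = paste0(.data$chrom, ":", .data$start, "-", .data$end))
    n_plant <- round(planted_fraction * nrow(base))
    planted_idx <- if (n_plant > 0) sample.int(nrow(base), n_plant) else integer(0)

    truth <- mutate(base, planted = FALSE, site_start = NA_integer_,
                    site_seq = NA_character_, site_score = NA_real_)
    seqs <- as.character(genome)
    for (i in planted_idx) {
      s <- .sample_site(pwm, threshold, background)
      pos <- truth$start[[i]] + (peak_length - L) %/% 2  # 0-based site start
      chr <- truth$chrom[[i]]
      substr(seqs[[chr]], pos + 1, pos + L) <- s
      truth$planted[[i]] <- TRUE
      truth$site_start[[i]] <- as.integer(pos)
      truth$site_seq[[i]] <- s
      truth$site_score[[i]] <- score_window(pwm, s, background)
    }
    genome_out <- Biostrings::DNAStringSet(seqs)

    jitter_rep <- function() {
      kept <- stats::runif(nrow(base)) >= dropout
      j1 <- if (jitter > 0) sample(-jitter:jitter, nrow(base), replace = TRUE) else 0L
      j2 <- if (jitter > 0) sample(-jitter:jitter, nrow(base), replace = TRUE) else 0L
      tibble(
        chrom = base$chrom,
        start = pmax(0L, as.integer(base$start + j1)),
        end = as.integer(pmin(chrom_len[base$chrom], base$end + j2))
      )[kept, ]
    }
    list(rep1 = jitter_rep(), rep2 = jitter_rep(), base_peaks = base,
         truth = truth, genome = genome_out)
  })
}

#' Simulate an organ-by-gene expression matrix with enriched genes
#'
#' Per-gene log-normal baselines with Gaussian replicate noise on the log2
#' scale; a planted subset of genes is shifted upward by `effect` log2
#' units in both focal organs.
#'
#' @param n_genes total genes.
#' @param organs organ labels; the first two are the focal pair.
#' @param n_enriched number of planted enriched genes.
#' @param effect log2 fold shift of enriched genes in the focal organs.
#' @param dispersion replicate noise standard deviation (log2 scale).
#' @param replicates samples per organ.
#' @param seed integer seed.
#' @return list: `mat` (genes x samples), `sample_info` (tibble `sample`,
#'   `organ`), `focal_organs`, `truth` (tibble `gene`, `enriched`).
#' @export
gen_expression <- function(n_genes = 1000,
                           organs = c("digestive_gland", "hepatopancreas",
                                      "gill", "mantle", "muscle"),
                           n_enriched = 50, effect = 2, dispersion = 0.3,
                           replicates = 3, seed = NULL) {
  if (n_enriched > n_genes) abort("`n_enriched` cannot exceed `n_genes`.")
  if (length(organs) < 3) abort("need the two focal organs plus at least one other.")
  focal <- organs[1:2]
  with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    enriched <- sample(genes, n_enriched)
    base_log2 <- stats::rnorm(n_genes, mean = 5, sd = 1.5)
    sample_info <- expand_grid(organ = organs, rep = seq_len(replicates)) |>
      mutate(sample = paste0(.data$organ, "_r", .data$rep)) |>
      select("sample", "organ")
    mat <- sapply(seq_len(nrow(sample_info)), function(j) {
      shift <- ifelse(genes %in% enriched & sample_info$organ[[j]] %in% focal,
                      effect, 0)
      2^(base_log2 + shift + stats::rnorm(n_genes, sd = dispersion))
    })
    dimnames(mat) <- list(genes, sample_info$sample)
    list(mat = mat, sample_info = sample_info, focal_organs = focal,
         truth = tibble(gene = genes, enriched = genes %in% enriched))
  })
}

#' Simulate a dual-luciferase measurement table
#'
#' Generates wells for a blank control (relative activity centred at 1),
#' two single-effector groups, and a combined group whose expected activity
#' follows the chosen effect model on the relative-activity scale:
#' `"additive"` adds the effector effects over the baseline
#' (`(mean_a - 1) + (mean_b - 1) + 1`), `"synergistic"` multiplies the
#' additive expectation by `synergy_factor`, `"sum"` draws each combined
#' well as an independent effector-A draw plus an independent effector-B
#' draw (the exact null of the pooled-sum test; its noise standard
#' deviation is therefore `sqrt(2) * noise_sd`), and `"null"` leaves every
#' group at baseline. Gaussian noise with standard deviation
#' `noise_sd` is added per well on the activity scale; activities are
#' encoded as firefly counts over a constant Renilla reading.
#'
#' @param mode effect model for the combined group.
#' @param mean_a,mean_b expected relative activities of the two effector
#'   groups.
#' @param noise_sd per-well Gaussian noise on the activity scale.
#' @param n_bio biological replicates per group.
#' @param n_tech technical replicates per biological replicate.
#' @param synergy_factor multiplier applied under `"synergistic"`.
#' @param seed integer seed.
#' @return list: `table` (tibble `group`, `bio_replicate`,
#'   `tech_replicate`, `firefly`, `renilla`), `truth` (tibble with the
#'   mode, group means and the expected combined-group mean), group labels
#'   `control_group`, `group_a`, `group_b`, `combined`.
#' @export
gen_luciferase <- function(mode = c("additive", "synergistic", "null", "sum"),
                           mean_a = 2, mean_b = 1.5, noise_sd = 0.1,
                           n_bio = 3, n_tech = 2, synergy_factor = 2,
                           seed = NULL) {
  mode <- match.arg(mode)
  if (synergy_factor <= 0) abort("`synergy_factor` must be positive.")
  additive <- (mean_a - 1) + (mean_b - 1) + 1
  combined_mean <- switch(mode,
    null = 1,
    additive = additive,
    synergistic = additive * synergy_factor,
    sum = mean_a + mean_b
  )
  means <- c(blank = 1,
             effector_a = if (mode == "null") 1 else mean_a,
             effector_b = if (mode == "null") 1 else mean_b,
             combined = combined_mean)
  renilla <- 100
  with_seed(seed, {
    table <- expand_grid(group = names(means), bio_replicate = seq_len(n_bio),
                         tech_replicate = seq_len(n_tech)) |>
      mutate(
        # a "sum" combined well is the sum of two independent draws, so its
        # noise variance is twice the single-effector variance
        sd_well = ifelse(mode == "sum" & .data$group == "combined",
                         noise_sd * sqrt(2), noise_sd),
        activity = pmax(0.01, means[.data$group] +
                          stats::rnorm(dplyr::n(), sd = .data$sd_well)),
        firefly = .data$activity * renilla,
        renilla = renilla
      ) |>
      select("group", "bio_replicate", "tech_replicate", "firefly", "renilla")
    list(
      table = table,
      truth = tibble(mode = mode, mean_a = means[["effector_a"]],
                     mean_b = means[["effector_b"]],
                     synergy_factor = if (mode == "synergistic") synergy_factor else 1,
                     expected_combined = combined_mean),
      control_group = "blank", group_a = "effector_a", group_b = "effector_b",
      combined = "combined"
    )
  })
}

#' Simulate a ChIP-qPCR Ct table with known fold enrichment
#'
#' Mock-IgG IP Cts sit at `ct_base`; specific-antibody IP Cts are lowered
#' by log2 of the true fold enrichment. Input Cts are shared between the
#' two antibodies within a replicate. Gaussian noise is added to the IP
#' Cts.
#'
#' @param true_fe true fold enrichment (> 0).
#' @param ct_base mock IP Ct level.
#' @param input_ct input-fraction Ct level.
#' @param noise_sd Ct noise standard deviation on the IP rows.
#' @param replicates number of replicates.
#' @param site site label.
#' @param seed integer seed.
#' @return list: `table` (tibble `site`, `antibody`, `fraction`,
#'   `replicate`, `ct`), `truth` (tibble `site`, `true_fe`).
#' @export
gen_chip <- function(true_fe = 2.2, ct_base = 30, input_ct = 25,
                     noise_sd = 0.15, replicates = 4, site = "site_1",
                     seed = NULL) {
  if (true_fe <= 0) abort("`true_fe` must be positive.")
  with_seed(seed, {
    reps <- seq_len(replicates)
    input <- input_ct + stats::rnorm(replicates, sd = noise_sd / 2)
    rows <- list(
      tibble(site = site, antibody = "specific", fraction = "ip",
             replicate = reps,
             ct = ct_base - log2(true_fe) + stats::rnorm(replicates, sd = noise_sd)),
      tibble(site = site, antibody = "mock_igg", fraction = "ip",
             replicate = reps,
             ct = ct_base + stats::rnorm(replicates, sd = noise_sd)),
      tibble(site = site, antibody = "specific", fraction = "input",
             replicate = reps, ct = input),
      tibble(site = site, antibody = "mock_igg", fraction = "input",
             replicate = reps, ct = input)
    )
    list(table = list_rbind(rows), truth = tibble(site = site, true_fe = true_fe))
  })
}

#' Random PWM generator
#'
#' Draws a motif by sampling each position from a Dirichlet distribution
#' whose mean puts `info` probability on a randomly chosen dominant base
#' and spreads the remainder evenly. The draws are continuous, so distinct
#' windows essentially never tie on score — important when the motif feeds
#' empirical threshold calibration.
#'
#' @param width motif width (>= 4).
#' @param info expected probability mass on the dominant base per position.
#' @param id motif identifier.
#' @param concentration Dirichlet concentration; larger values keep
#'   positions closer to the `info` target.
#' @param seed integer seed.
#' @return a [pwm()].
#' @export
gen_pwm <- function(width = 10, info = 0.85, id = "sim_motif",
                    concentration = 60, seed = NULL) {
  check_probability(info, "info", allow_one = FALSE)
  with_seed(seed, {
    mat <- t(vapply(seq_len(width), function(i) {
      shape <- rep((1 - info) / 3, 4)
      shape[sample.int(4, 1)] <- info
      g <- stats::rgamma(4, shape = shape * concentration)
      g / sum(g)
    }, numeric(4)))
    pwm(mat, id = id)
  })
}

#' Perturb a PWM with Gaussian noise
#'
#' Adds Gaussian noise to every probability entry and renormalizes each
#' position; used to build families of related motifs with controlled
#' similarity for clustering simulations.
#'
#' @param x a [pwm()].
#' @param sd noise standard deviation on the probability scale.
#' @param id identifier for the perturbed motif.
#' @param seed integer seed.
#' @return a [pwm()].
#' @export
perturb_pwm <- function(x, sd = 0.02, id = paste0(x$id, "_pert"), seed = NULL) {
  stopifnot(inherits(x, "pwm"))
  with_seed(seed, {
    mat <- pmax(x$matrix + stats::rnorm(length(x$matrix), sd = sd), 1e-4)
    pwm(mat, id = id, pseudocount = x$pseudocount)
  })
}
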