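#' Simulation configuration for a synthetic cervicovaginal methylation cohort
#'
#' Bundles every parameter the cohort simulator needs: cohort size, screen
#' size, the planted marker-region design, the epithelial/immune mixture
#' model, and the qPCR dropout rate. Defaults describe the study conditions
#' used throughout the package: 100 cases and 100 controls measured at 2,000
#' CpGs with three planted hypermethylated regions of five CpGs each.
#'
#' @param n_cases,n_controls Number of cancer cases and controls.
#' @param n_cpgs Number of CpGs on the simulated screen.
#' @param n_true_regions Number of planted cancer marker regions.
#' @param cpgs_per_region CpGs per planted region.
#' @param region_span_bp Maximum genomic span of a planted region, in base
#'   pairs.
#' @param effect_size Methylation-fraction increase in the epithelial
#'   compartment of cases at planted CpGs; in \[0, 1\], with 0 giving a
#'   null simulation.
#' @param immune_shape1,immune_shape2 Shape parameters of the Beta
#'   distribution from which per-sample immune cell fractions are drawn.
#' @param noise_sd Standard deviation of additive Gaussian noise on the beta
#'   scale (values clipped back to \[0, 1\]).
#' @param dropout_rate Probability that a sample yields insufficient DNA and
#'   fails qPCR quality control; in \[0, 1).
#' @param seed Integer seed governing the simulation.
#'
#' @return A list of class `wq_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 10, n_controls = 10, n_cpgs = 500)
sim_config <- function(n_cases = 100L, n_controls = 100L, n_cpgs = 2000L,
                       n_true_regions = 3L, cpgs_per_region = 5L,
                       region_span_bp = 500L, effect_size = 0.3,
                       immune_shape1 = 2, immune_shape2 = 5,
                       noise_sd = 0.05, dropout_rate = 0.137, seed = 1L) {
  counts <- c(n_cases = n_cases, n_controls = n_controls, n_cpgs = n_cpgs,
              n_true_regions = n_true_regions,
              cpgs_per_region = cpgs_per_region,
              region_span_bp = region_span_bp)
  if (any(counts <= 0)) {
    stop("all counts must be positive: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  }
  if (effect_size < 0 || effect_size > 1) {
    stop("effect_size must be in [0, 1] (0 simulates the null)")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_cpgs = as.integer(n_cpgs),
                 n_true_regions = as.integer(n_true_regions),
                 cpgs_per_region = as.integer(cpgs_per_region),
                 region_span_bp = as.integer(region_span_bp),
                 effect_size = effect_size,
                 immune_shape1 = immune_shape1,
                 immune_shape2 = immune_shape2,
                 noise_sd = noise_sd,
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "wq_sim_config")
}

#' Generate reference methylation profiles for the two-compartment model
#'
#' Lays `n_cpgs` CpGs along four synthetic chromosomes and assigns each an
#' epithelial and an immune mean methylation fraction. A documented fraction
#' of CpGs is "discoverable" — essentially unmethylated in both healthy
#' epithelium and immune cells, so that cancer-specific epithelial
#' hypermethylation is detectable against a clean background. Discoverable
#' CpGs come in tight genomic blocks (intra-block spacing 60-110 bp) so that
#' planted marker regions satisfy proximity clustering; the remaining CpGs
#' carry arbitrary baseline methylation and wide spacing.
#'
#' @param n_cpgs Number of CpGs; at least 100.
#' @param seed Integer seed.
#' @param discoverable_fraction Fraction of CpGs placed in discoverable
#'   blocks (default 0.2).
#' @param block_size Number of consecutive CpGs per discoverable block.
#'
#' @return A data frame of class `wq_reference_profiles` with columns
#'   `cpg_id`, `chrom`, `pos` (0-based), `epithelial_mean`, `immune_mean`,
#'   `discoverable`.
#' @export
generate_reference_profiles <- function(n_cpgs, seed = 1L,
                                        discoverable_fraction = 0.2,
                                        block_size = 10L) {
  if (n_cpgs < 100) stop("n_cpgs must be at least 100")
  set.seed(seed)
  chroms <- paste0("chr", 1:4)
  per_chrom <- diff(round(seq(0, n_cpgs, length.out = length(chroms) + 1)))
  n_blocks_total <- max(1L, floor(discoverable_fraction * n_cpgs / block_size))

  rows <- vector("list", length(chroms))
  blocks_left <- n_blocks_total
  for (k in seq_along(chroms)) {
    m <- per_chrom[k]
    n_blocks <- if (k < length(chroms)) {
      round(n_blocks_total * m / n_cpgs)
    } else {
      blocks_left
    }
    n_blocks <- max(0L, min(n_blocks, blocks_left, floor(m / (2L * block_size))))
    blocks_left <- blocks_left - n_blocks

    disc <- rep(FALSE, m)
    if (n_blocks > 0) {
      stride <- floor(m / n_blocks)
      for (b in seq_len(n_blocks)) {
        lo <- (b - 1L) * stride + 1L
        start <- lo + sample.int(max(1L, stride - block_size), 1L) - 1L
        disc[start:min(start + block_size - 1L, m)] <- TRUE
      }
    }
    # tight spacing inside discoverable blocks, wide spacing elsewhere
    in_block_gap <- disc & c(FALSE, disc[-m])
    gaps <- ifelse(in_block_gap, runif(m, 60, 110), runif(m, 800, 3000))
    pos <- cumsum(round(gaps))
    rows[[k]] <- data.frame(chrom = chroms[k], pos = as.integer(pos),
                            discoverable = disc,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  n <- nrow(out)
  out$cpg_id <- sprintf("cg%07d", seq_len(n))
  out$epithelial_mean <- ifelse(out$discoverable,
                                runif(n, 0, 0.05), runif(n, 0.1, 0.9))
  out$immune_mean <- ifelse(out$discoverable,
                            runif(n, 0, 0.05), runif(n, 0.1, 0.9))
  out <- out[, c("cpg_id", "chrom", "pos", "epithelial_mean", "immune_mean",
                 "discoverable")]
  class(out) <- c("wq_reference_profiles", "data.frame")
  out
}

# pick n_true_regions runs of consecutive discoverable CpGs, each giving
# cpgs_per_region members within region_span_bp
select_planted_regions <- function(profiles, config) {
  need <- config$n_true_regions * config$cpgs_per_region
  if (sum(profiles$discoverable) < need) {
    stop("insufficient discoverable CpGs: need ", need, ", have ",
         sum(profiles$discoverable))
  }
  candidates <- list()
  for (ch in unique(profiles$chrom)) {
    p <- profiles[profiles$chrom == ch, ]
    r <- rle(p$discoverable)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= config$cpgs_per_region)) {
      idx <- starts[i]:ends[i]
      # first window of cpgs_per_region consecutive CpGs fitting the span
      for (off in 0:(length(idx) - config$cpgs_per_region)) {
        w <- idx[(off + 1):(off + config$cpgs_per_region)]
        if (p$pos[w[length(w)]] - p$pos[w[1]] <= config$region_span_bp) {
          candidates[[length(candidates) + 1L]] <- p$cpg_id[w]
          break
        }
      }
    }
  }
  if (length(candidates) < config$n_true_regions) {
    stop("profiles contain only ", length(candidates),
         " discoverable clusters tight enough for planting; need ",
         config$n_true_regions)
  }
  candidates[sort(sample.int(length(candidates), config$n_true_regions))]
}

#' Simulate a mixed-cell beta-value matrix with planted marker regions
#'
#' Generates per-sample methylation as a two-component cell mixture: for
#' sample i and CpG j,
#' `beta[i, j] = clip((1 - f_i) * epi_ij + f_i * immune_j + eps, 0, 1)`,
#' where `f_i` is the sample's immune cell fraction (Beta-distributed),
#' `eps` is Gaussian noise, and `epi_ij` equals the epithelial reference
#' mean plus `effect_size` for cases at planted CpGs. Cancer
#' hypermethylation is thus confined to the epithelial compartment, so the
#' case signal is diluted in samples with high immune contamination.
#'
#' Cohort metadata emulate a symptomatic triage population: ages around the
#' postmenopausal peak, stage/grade/histology for cases, and two numeric
#' comparator measurements per sample (endometrial thickness in mm and a
#' somatic mutation count) with case/control separation typical of
#' ultrasound and mutation testing.
#'
#' @param config A [sim_config()] object.
#' @param profiles Reference profiles from [generate_reference_profiles()].
#' @param predictive If `TRUE`, cases receive a months-to-diagnosis value
#'   uniform on (0, 36) months (a screening-archive design); otherwise
#'   `months_to_event` is `NA` (diagnostic setting).
#' @param planted Optional list of CpG-id vectors fixing the planted
#'   marker regions, so several cohorts (discovery, pilot, validation)
#'   share the same disease biology; by default regions are selected from
#'   the profiles under the config seed.
#' @param immune_fractions Optional fixed per-sample immune fractions in
#'   \[0, 1\] (overrides the Beta draw; useful for degenerate-mixture
#'   checks).
#'
#' @return A list of class `wq_cohort` with elements `beta` (samples x CpGs
#'   matrix), `meta` (sample sheet data frame), `truth` (planted region
#'   table with member CpG ids), and `immune_fractions`.
#' @export
simulate_beta_matrix <- function(config, profiles, predictive = FALSE,
                                 planted = NULL, immune_fractions = NULL) {
  stopifnot(inherits(config, "wq_sim_config"),
            inherits(profiles, "wq_reference_profiles"))
  set.seed(config$seed)
  if (is.null(planted)) {
    planted <- select_planted_regions(profiles, config)
  }
  planted_ids <- unlist(planted)

  n <- config$n_cases + config$n_controls
  sample_id <- sprintf("S%04d", seq_len(n))
  group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  is_case <- group == "case"
  f <- if (is.null(immune_fractions)) {
    rbeta(n, config$immune_shape1, config$immune_shape2)
  } else {
    stopifnot(length(immune_fractions) == n,
              all(immune_fractions >= 0 & immune_fractions <= 1))
    as.numeric(immune_fractions)
  }
  months_to_event <- if (predictive) {
    ifelse(is_case, round(runif(n, 0, 36), 1), NA)
  } else {
    rep(NA_real_, n)
  }
  # in predictive (pre-diagnosis) settings the tumour signal grows toward
  # diagnosis: the planted effect halves for every 12 months of lead time
  effect <- rep(config$effect_size, n)
  if (predictive) {
    effect[is_case] <- config$effect_size *
      2^(-months_to_event[is_case] / 12)
  }

  epi <- matrix(profiles$epithelial_mean, nrow = n, ncol = nrow(profiles),
                byrow = TRUE)
  imm <- matrix(profiles$immune_mean, nrow = n, ncol = nrow(profiles),
                byrow = TRUE)
  jp <- match(planted_ids, profiles$cpg_id)
  epi[is_case, jp] <- epi[is_case, jp] + effect[is_case]

  beta <- (1 - f) * epi + f * imm
  if (config$noise_sd > 0) {
    beta <- beta + matrix(rnorm(n * ncol(beta), sd = config$noise_sd),
                          nrow = n)
  }
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(sample_id, profiles$cpg_id)

  age <- pmin(pmax(round(rnorm(n, 64, 8)), 35), 90)
  meta <- data.frame(
    sample_id = sample_id,
    group = group,
    age = age,
    menopausal_status = ifelse(age >= 51, "post", "pre"),
    stage = ifelse(is_case,
                   sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                          prob = c(0.7, 0.1, 0.1, 0.1)), NA),
    grade = ifelse(is_case, sample(1:3, n, replace = TRUE), NA),
    histology = ifelse(is_case,
                       sample(c("endometrioid", "serous", "other"), n,
                              replace = TRUE, prob = c(0.8, 0.1, 0.1)), NA),
    collection = sample(c("smear", "self", "swab"), n, replace = TRUE),
    months_to_event = months_to_event,
    ultrasound_mm = round(pmax(ifelse(is_case, rnorm(n, 12, 4),
                                      rnorm(n, 4, 2)), 0.5), 1),
    n_mutations = ifelse(is_case, rpois(n, 1.2), rpois(n, 0.1)),
    stringsAsFactors = FALSE
  )

  truth <- do.call(rbind, lapply(seq_along(planted), function(i) {
    ids <- planted[[i]]
    j <- match(ids, profiles$cpg_id)
    data.frame(region_id = paste0("planted_", i),
               chrom = profiles$chrom[j[1]],
               start = min(profiles$pos[j]),
               end = max(profiles$pos[j]) + 1L,
               cpg_ids = paste(ids, collapse = ";"),
               stringsAsFactors = FALSE)
  }))

  structure(list(beta = beta, meta = meta, truth = truth,
                 immune_fractions = stats::setNames(f, sample_id)),
            class = "wq_cohort")
}

#' Simulate a MethyLight qPCR plate from ground-truth PMR values
#'
#' Converts per-sample, per-assay ground-truth PMR (percentage of methylated
#' reference) values into cycle-threshold measurements under a perfect
#' doubling model: the marker Ct sits `log2(PMR / 100)` cycles below the
#' sample's reference-assay Ct (fewer methylated copies mean later
#' amplification), plus optional Gaussian cycle noise. A PMR of exactly 0
#' yields an "undetermined" well (no amplification, stored as `NA`).
#' Fully methylated calibrator control wells are added for every assay with
#' a target/reference quantity ratio of 1 by construction. DNA-insufficient
#' samples (drawn with probability `dropout_rate`) receive a reference Ct
#' above the usual validity cutoff so downstream QC can reject them.
#'
#' @param true_pmr Numeric matrix (samples x assays, dimnames required) of
#'   non-negative ground-truth PMR values.
#' @param ref_ct_range Length-2 interval from which per-sample reference
#'   assay Cts are drawn uniformly, in cycles.
#' @param ct_noise_sd Standard deviation of Gaussian noise added to marker
#'   Cts, in cycles.
#' @param dropout_rate Probability a sample is DNA-insufficient.
#' @param seed Integer seed.
#' @param dropout_ref_ct_range Reference-Ct interval for DNA-insufficient
#'   samples; must sit above the QC cutoff in use (default 40-45 cycles).
#' @param ref_assay Name of the reference (methylation-independent) assay.
#' @param calibrator_ct Ct assigned to all calibrator wells.
#'
#' @return A data frame of class `wq_qpcr_plate` with columns `sample_id`,
#'   `assay_id`, `replicate`, `ct` (numeric, `NA` = undetermined),
#'   `is_calibrator` (0/1).
#' @export
simulate_qpcr_plate <- function(true_pmr, ref_ct_range = c(24, 30),
                                ct_noise_sd = 0, dropout_rate = 0,
                                seed = 1L,
                                dropout_ref_ct_range = c(40, 45),
                                ref_assay = "COL2A1",
                                calibrator_ct = 25) {
  if (!is.matrix(true_pmr) || is.null(rownames(true_pmr)) ||
      is.null(colnames(true_pmr))) {
    stop("true_pmr must be a matrix with sample rownames and assay colnames")
  }
  if (any(true_pmr < 0)) stop("PMR values must be non-negative")
  if (ref_assay %in% colnames(true_pmr)) {
    stop("ref_assay name collides with a marker assay")
  }
  set.seed(seed)
  samples <- rownames(true_pmr)
  assays <- colnames(true_pmr)
  n <- length(samples)

  dropout <- runif(n) < dropout_rate
  ref_ct <- ifelse(dropout,
                   runif(n, dropout_ref_ct_range[1], dropout_ref_ct_range[2]),
                   runif(n, ref_ct_range[1], ref_ct_range[2]))

  marker <- do.call(rbind, lapply(seq_along(assays), function(j) {
    pmr <- true_pmr[, j]
    ct <- ref_ct - log2(pmr / 100)     # pmr = 0 -> Inf -> undetermined
    if (ct_noise_sd > 0) ct <- ct + rnorm(n, sd = ct_noise_sd)
    ct[!is.finite(ct)] <- NA_real_
    data.frame(sample_id = samples, assay_id = assays[j], replicate = 1L,
               ct = ct, is_calibrator = 0L, stringsAsFactors = FALSE)
  }))
  reference <- data.frame(sample_id = samples, assay_id = ref_assay,
                          replicate = 1L, ct = ref_ct, is_calibrator = 0L,
                          stringsAsFactors = FALSE)
  calibrator <- data.frame(sample_id = "CALIBRATOR",
                           assay_id = c(assays, ref_assay), replicate = 1L,
                           ct = calibrator_ct, is_calibrator = 1L,
                           stringsAsFactors = FALSE)
  plate <- rbind(marker, reference, calibrator)
  rownames(plate) <- NULL
  class(plate) <- c("wq_qpcr_plate", "data.frame")
  plate
}
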