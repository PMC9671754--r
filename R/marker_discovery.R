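#' Estimate the immune cell fraction of a sample from its methylation profile
#'
#' Models the sample as a two-component mixture of epithelial and immune
#' cells and finds the immune fraction `f` minimizing the sum of squared
#' differences between the observed beta values and
#' `(1 - f) * epithelial_mean + f * immune_mean`. The unconstrained
#' least-squares solution is closed-form and is projected onto \[0, 1\].
#'
#' @param beta_row Numeric vector of beta values aligned to `profiles`'
#'   CpGs (at least 10 CpGs).
#' @param profiles Reference profiles ([generate_reference_profiles()]).
#' @return Estimated immune fraction in \[0, 1\]; `NA` with a warning when
#'   the epithelial and immune profiles are identical at every CpG (the
#'   mixture is unidentifiable).
#' @seealso [estimate_immune_fractions()] for the matrix version.
#' @export
estimate_immune_fraction <- function(beta_row, profiles) {
  stopifnot(length(beta_row) == nrow(profiles))
  if (length(beta_row) < 10) stop("need at least 10 CpGs")
  d <- profiles$immune_mean - profiles$epithelial_mean
  ss <- sum(d^2)
  if (ss == 0) {
    warning("epithelial and immune profiles identical: immune fraction ",
            "unidentifiable")
    return(NA_real_)
  }
  f <- sum((beta_row - profiles$epithelial_mean) * d) / ss
  min(max(f, 0), 1)
}

#' Estimate immune fractions for every sample in a beta matrix
#'
#' @param beta Samples x CpGs matrix with CpG column names matching
#'   `profiles$cpg_id`.
#' @param profiles Reference profiles.
#' @return Named numeric vector of immune fractions in \[0, 1\].
#' @export
estimate_immune_fractions <- function(beta, profiles) {
  stopifnot(identical(colnames(beta), profiles$cpg_id))
  d <- profiles$immune_mean - profiles$epithelial_mean
  ss <- sum(d^2)
  if (ss == 0) {
    warning("epithelial and immune profiles identical: immune fraction ",
            "unidentifiable")
    return(stats::setNames(rep(NA_real_, nrow(beta)), rownames(beta)))
  }
  f <- as.numeric(sweep(beta, 2, profiles$epithelial_mean) %*% d) / ss
  stats::setNames(pmin(pmax(f, 0), 1), rownames(beta))
}

#' Rank CpGs for case/control discrimination with immune-fraction adjustment
#'
#' The discovery screen for MethyLight-amenable markers. A CpG is eligible
#' when it is essentially unmethylated both in immune cells
#' (`immune_reference_methylation <= immune_cap`) and in control epithelium
#' (`control_epithelial_methylation <= control_cap`), so a PCR signal in a
#' contaminated cervicovaginal specimen can only come from tumour-derived
#' epithelial hypermethylation. Each eligible CpG is scored by the
#' case-indicator t-statistic from the per-CpG least-squares fit
#' `beta ~ intercept + case + immune_fraction`, which adjusts the
#' case/control contrast for immune contamination; CpGs are ranked by
#' descending statistic, ties broken by genomic order.
#'
#' Control epithelial methylation is estimated per CpG by inverting the
#' mixture in control samples,
#' `(beta - f * immune_mean) / (1 - f)` averaged over controls with
#' `f < 0.95`, clipped to \[0, 1\].
#'
#' @param beta Samples x CpGs beta matrix.
#' @param labels Character vector, `"case"` or `"control"` per sample.
#' @param immune_fractions Per-sample immune fractions (from
#'   [estimate_immune_fractions()] or ground truth).
#' @param profiles Reference profiles supplying the immune reference
#'   methylation for the eligibility screen.
#' @param immune_cap,control_cap Eligibility caps on immune reference and
#'   control epithelial methylation (defaults 0.2).
#' @return A data frame of class `wq_cpg_ranking` with one row per CpG:
#'   `cpg_id`, `chrom`, `pos`, `statistic`, `rank` (`NA` for ineligible
#'   CpGs), `immune_reference_methylation`,
#'   `control_epithelial_methylation`, `eligible`.
#' @export
rank_cpgs <- function(beta, labels, immune_fractions, profiles,
                      immune_cap = 0.2, control_cap = 0.2) {
  stopifnot(identical(colnames(beta), profiles$cpg_id),
            length(labels) == nrow(beta),
            length(immune_fractions) == nrow(beta))
  if (!all(labels %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  if (sum(labels == "case") < 2 || sum(labels == "control") < 2) {
    stop("need at least 2 cases and 2 controls")
  }

  f <- as.numeric(immune_fractions)
  is_ctrl <- labels == "control"
  usable <- is_ctrl & f < 0.95
  w <- 1 / (1 - f[usable])
  # invert the two-component mixture in controls to recover the epithelial
  # compartment's methylation
  epi_ctrl <- (beta[usable, , drop = FALSE] -
                 outer(f[usable], profiles$immune_mean)) * w
  control_epi <- pmin(pmax(colMeans(epi_ctrl), 0), 1)

  eligible <- profiles$immune_mean <= immune_cap & control_epi <= control_cap

  # vectorised per-CpG least squares: beta_j ~ 1 + case + immune_fraction;
  # a constant immune fraction carries no information and would make the
  # design singular, so it is dropped from the model
  X <- cbind(1, as.numeric(labels == "case"), f)
  if (stats::var(f) < 1e-12) X <- X[, 1:2, drop = FALSE]
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, beta)            # 3 x p coefficients
  resid <- beta - X %*% B
  df <- nrow(beta) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtXi[2, 2])
  # an (effectively) exact fit means no variance to explain: statistic 0
  tstat <- ifelse(se > 1e-8, B[2, ] / se, 0)

  out <- data.frame(cpg_id = profiles$cpg_id, chrom = profiles$chrom,
                    pos = profiles$pos, statistic = as.numeric(tstat),
                    rank = NA_integer_,
                    immune_reference_methylation = profiles$immune_mean,
                    control_epithelial_methylation = control_epi,
                    eligible = eligible, stringsAsFactors = FALSE)
  ranked <- which(eligible & out$statistic != 0)
  if (length(ranked) > 0) {
    ord <- ranked[order(-out$statistic[ranked], out$chrom[ranked],
                        out$pos[ranked])]
    out$rank[ord] <- seq_along(ord)
  }
  class(out) <- c("wq_cpg_ranking", "data.frame")
  out
}

#' Build candidate marker regions from top-ranked CpGs by genomic proximity
#'
#' Takes the `top_n` ranked CpGs as seeds, collects all ranked CpGs within
#' `window_bp` of each seed on the same chromosome, merges clusters that
#' share members (transitively), and keeps clusters with at least
#' `min_cpgs` members. Region intervals are 0-based half-open, spanning the
#' minimum to maximum member position plus one.
#'
#' @param ranking A `wq_cpg_ranking` from [rank_cpgs()].
#' @param top_n Number of top-ranked CpGs used as cluster seeds.
#' @param window_bp Proximity window around each seed, in base pairs
#'   (default 500).
#' @param min_cpgs Minimum cluster size for a region to be kept.
#' @return A data frame of class `wq_regions`: `region_id`, `chrom`,
#'   `start`, `end`, `n_cpgs`, `cpg_ids` (semicolon-separated), `auc`
#'   (`NA` until scored), ordered by genomic position.
#' @export
build_regions <- function(ranking, top_n, window_bp = 500L, min_cpgs = 3L) {
  ranked <- ranking[!is.na(ranking$rank), , drop = FALSE]
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_cpgs = integer(), cpg_ids = character(),
                      auc = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("wq_regions", "data.frame")
  if (nrow(ranked) == 0) return(empty)

  seeds <- ranked[ranked$rank <= top_n, , drop = FALSE]
  clusters <- lapply(seq_len(nrow(seeds)), function(i) {
    same <- ranked$chrom == seeds$chrom[i] &
      abs(ranked$pos - seeds$pos[i]) <= window_bp
    ranked$cpg_id[same]
  })
  # transitive merge of clusters sharing members
  merged <- list()
  for (cl in clusters) {
    hit <- which(vapply(merged, function(m) any(cl %in% m), logical(1)))
    if (length(hit) == 0) {
      merged[[length(merged) + 1L]] <- cl
    } else {
      merged[[hit[1]]] <- unique(c(unlist(merged[hit]), cl))
      if (length(hit) > 1) merged <- merged[-hit[-1]]
    }
  }
  keep <- Filter(function(m) length(m) >= min_cpgs, merged)
  if (length(keep) == 0) return(empty)

  out <- do.call(rbind, lapply(keep, function(ids) {
    j <- match(ids, ranked$cpg_id)
    data.frame(chrom = ranked$chrom[j[1]],
               start = min(ranked$pos[j]),
               end = max(ranked$pos[j]) + 1L,
               n_cpgs = length(ids),
               cpg_ids = paste(ids[order(ranked$pos[j])], collapse = ";"),
               auc = NA_real_, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(region_id = sprintf("region_%02d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("wq_regions", "data.frame")
  out
}

#' Score samples on a candidate region (array surrogate for a MethyLight
#' reaction)
#'
#' @param beta Samples x CpGs beta matrix.
#' @param region One row of a `wq_regions` data frame (or any list with a
#'   `cpg_ids` field of semicolon-separated CpG ids).
#' @return Named per-sample score: mean beta over the region's member CpGs.
#' @export
region_score <- function(beta, region) {
  ids <- strsplit(region$cpg_ids, ";", fixed = TRUE)[[1]]
  missing <- setdiff(ids, colnames(beta))
  if (length(missing) > 0) {
    stop("CpGs absent from beta matrix: ", paste(missing, collapse = ", "))
  }
  rowMeans(beta[, ids, drop = FALSE])
}

#' Rank candidate reactions by AUC and select the panel
#'
#' Computes the empirical AUC of each candidate's per-sample score for
#' case/control discrimination and orders candidates by descending AUC,
#' ties broken by genomic position. The top `k` (three, for the assay
#' panel) are the selected reactions.
#'
#' @param scores Samples x candidates matrix of per-sample region scores
#'   (column names are region ids), or a `wq_regions` table plus `beta`.
#' @param labels `"case"` / `"control"` per sample.
#' @param regions The `wq_regions` table the score columns refer to.
#' @return The `regions` table with `auc` filled in, ordered by descending
#'   AUC (ties by chrom, start).
#' @export
rank_reactions_by_auc <- function(scores, labels, regions) {
  if (length(unique(labels)) < 2) {
    stop("both cases and controls are required to rank by AUC")
  }
  if (nrow(regions) == 0) return(regions)
  stopifnot(identical(colnames(scores), regions$region_id))
  auc <- vapply(seq_len(ncol(scores)), function(j) {
    roc_auc(scores[, j], labels)$auc
  }, numeric(1))
  regions$auc <- auc
  ord <- order(-auc, regions$chrom, regions$start)
  out <- regions[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full marker-discovery stage on a cohort
#'
#' Convenience wrapper: estimates immune fractions, ranks CpGs, builds
#' proximity regions from the top-ranked CpGs, scores them, and ranks the
#' candidate reactions by AUC.
#'
#' @param beta Samples x CpGs beta matrix.
#' @param labels `"case"` / `"control"` per sample.
#' @param profiles Reference profiles.
#' @param top_n Seeds taken from the CpG ranking.
#' @param window_bp Proximity window (bp).
#' @param min_cpgs Minimum CpGs per region.
#' @param top_k Number of reactions selected for the panel.
#' @param immune_cap,control_cap Eligibility caps passed to [rank_cpgs()].
#' @return List with `immune_fractions`, `ranking`, `regions` (all
#'   candidates, AUC-ranked) and `panel` (top `top_k` rows).
#' @export
discover_markers <- function(beta, labels, profiles, top_n = 30L,
                             window_bp = 500L, min_cpgs = 3L, top_k = 3L,
                             immune_cap = 0.2, control_cap = 0.2) {
  f <- estimate_immune_fractions(beta, profiles)
  ranking <- rank_cpgs(beta, labels, f, profiles,
                       immune_cap = immune_cap, control_cap = control_cap)
  regions <- build_regions(ranking, top_n = top_n, window_bp = window_bp,
                           min_cpgs = min_cpgs)
  if (nrow(regions) == 0) {
    return(list(immune_fractions = f, ranking = ranking, regions = regions,
                panel = regions))
  }
  scores <- vapply(seq_len(nrow(regions)),
                   function(i) region_score(beta, regions[i, ]),
                   numeric(nrow(beta)))
  colnames(scores) <- regions$region_id
  ranked <- rank_reactions_by_auc(scores, labels, regions)
  list(immune_fractions = f, ranking = ranking, regions = ranked,
       panel = ranked[seq_len(min(top_k, nrow(ranked))), , drop = FALSE])
}
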