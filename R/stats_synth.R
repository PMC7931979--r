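#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by the step-up rule:
#' with the m non-missing p-values sorted ascending, the adjusted value at
#' rank i is `min over j >= i of (p_j * m / j)`, clipped at 1, and results
#' are returned in the input order. Missing p-values are excluded from m and
#' returned as missing.
#'
#' @param p numeric vector of p-values in `[0, 1]`; NA allowed.
#' @return numeric vector of BH-adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  p <- as.double(p)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  o <- order(p[ok])
  ps <- p[ok][o]
  q <- rev(cummin(rev(ps * m / seq_len(m))))
  out[ok[o]] <- pmin(q, 1)
  out
}

#' Welch two-group statistics per feature
#'
#' Computes, for every feature, the difference of group means (the log2 fold
#' change when the matrix is on the log2 scale), the overall average level,
#' a Welch (unequal-variance) t-test p-value, and BH-adjusted p-values.
#' This is a stand-in for upstream moderated models, intended mainly for
#' synthetic data; it is not a replacement for limma/DESeq2 on real data.
#'
#' A feature needs at least two non-missing values per group for a p-value.
#' Features where both groups have zero variance get p = 1 when the means
#' are equal (no evidence of change) and a missing p when they differ (the
#' t statistic is undefined); the fold change is reported either way.
#'
#' @param ds an [omic_dataset].
#' @param group_column design column defining the groups.
#' @param level_a,level_b the two group levels; log2fc = mean(a) - mean(b).
#' @return a [contrast_stats] named `"<level_a>_vs_<level_b>"`.
#' @export
two_group_stats <- function(ds, group_column, level_a, level_b) {
  stopifnot(inherits(ds, "omic_dataset"))
  if (!group_column %in% names(ds$design))
    stop(sprintf("group column '%s' not in design; available: %s",
                 group_column, paste(names(ds$design), collapse = ", ")),
         call. = FALSE)
  grp <- as.character(ds$design[[group_column]])
  samp <- as.character(ds$design[[ds$sample_column]])
  cols_a <- intersect(samp[grp == level_a], colnames(ds$matrix))
  cols_b <- intersect(samp[grp == level_b], colnames(ds$matrix))
  if (length(cols_a) == 0L || length(cols_b) == 0L)
    stop(sprintf("groups '%s'/'%s' not found in column '%s'",
                 level_a, level_b, group_column), call. = FALSE)
  A <- ds$matrix[, cols_a, drop = FALSE]
  B <- ds$matrix[, cols_b, drop = FALSE]

  na <- rowSums(!is.na(A)); nb <- rowSums(!is.na(B))
  ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
  rowvar <- function(X, mu, n) {
    v <- rowSums((X - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
    v[n < 2] <- NA_real_
    v
  }
  va <- rowvar(A, ma, na); vb <- rowvar(B, mb, nb)
  ma[na == 0] <- NA_real_; mb[nb == 0] <- NA_real_

  lfc <- ma - mb
  ave <- rowMeans(cbind(A, B), na.rm = TRUE)
  ave[na + nb == 0] <- NA_real_

  se2 <- va / na + vb / nb
  p <- rep(NA_real_, nrow(A))
  usable <- na >= 2 & nb >= 2 & !is.na(se2)
  pos <- usable & se2 > 0
  if (any(pos)) {
    tstat <- lfc[pos] / sqrt(se2[pos])
    df <- se2[pos]^2 /
      ((va[pos] / na[pos])^2 / (na[pos] - 1) +
       (vb[pos] / nb[pos])^2 / (nb[pos] - 1))
    p[pos] <- 2 * stats::pt(-abs(tstat), df)
  }
  degen <- usable & se2 == 0
  p[degen & lfc == 0] <- 1
  # degenerate with nonzero difference stays NA: t is infinite/undefined
  contrast_stats(paste0(level_a, "_vs_", level_b), p = p,
                 fdr = bh_adjust(p), log2fc = lfc, ave = ave)
}

#' Expected log2 fold change of a known spike-in design
#'
#' In a two-organism spike-in benchmark where a species' proteins are mixed
#' at one weight fraction in condition one and another in condition two, the
#' true abundance ratio is known and the expected log2 fold change is simply
#' `log2(conc_a / conc_b)` — e.g. 30\% vs 3\% w/w gives 3.3.
#'
#' @param conc_a,conc_b spike-in concentrations (any shared unit).
#' @return expected log2 fold change.
#' @export
spikein_expected_lfc <- function(conc_a, conc_b) log2(conc_a / conc_b)

# Run `code` under a fixed seed, restoring the caller's RNG state after.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic spike-in world
#'
#' Describes a two-condition benchmark in the spirit of a two-organism
#' spike-in experiment: a large background of unchanged features plus known
#' sets of truly up- and down-regulated features whose condition means
#' differ by a fixed log2 fold (the reversed 30\%/3\% w/w design gives
#' log2 fold 3.3). Defaults follow that benchmark: three replicates per
#' condition, true log2 fold 3.3; the noise level (0.5 log2 units, a typical
#' replicate CV for label-free proteomics) and the 1800/100/100 feature
#' split are this generator's own choices.
#'
#' @param n_background number of null features.
#' @param n_up,n_down numbers of truly up-/down-regulated features.
#' @param true_lfc true log2 fold change of the changed features.
#' @param noise_sd replicate noise standard deviation, log2 units.
#' @param n_replicates replicates per condition (>= 2).
#' @param missing_rate fraction of cells masked missing, in `[0, 1)`.
#' @param baseline_mean,baseline_sd distribution of per-feature baseline
#'   log2 intensities.
#' @param seed RNG seed (mandatory: simulations are reproducible by design).
#' @return a `spikein_design` parameter list.
#' @export
spikein_design <- function(n_background = 1800, n_up = 100, n_down = 100,
                           true_lfc = 3.3, noise_sd = 0.5,
                           n_replicates = 3, missing_rate = 0,
                           baseline_mean = 20, baseline_sd = 2, seed) {
  stopifnot(n_background >= 0, n_up >= 0, n_down >= 0, noise_sd >= 0,
            n_replicates >= 2, missing_rate >= 0, missing_rate < 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  structure(as.list(environment()), class = "spikein_design")
}

#' Simulate a two-condition spike-in benchmark dataset
#'
#' Generates a feature-by-sample log2 matrix under a [spikein_design()]:
#' background features share the same mean in both conditions; changed
#' features differ by plus/minus `true_lfc`. Gaussian replicate noise is
#' added and cells are masked missing at `missing_rate`. The same design and
#' seed always reproduce the same dataset bit for bit.
#'
#' @param d a [spikein_design()].
#' @param name dataset label.
#' @return list with `dataset` (an [omic_dataset], design column `condition`
#'   with levels `c1`/`c2`) and `truth` (data.frame: `feature_id`, `class`
#'   in background/up/down, `true_lfc`).
#' @export
simulate_spikein <- function(d, name = "spikein") {
  stopifnot(inherits(d, "spikein_design"))
  .with_seed(d$seed, {
    n <- d$n_background + d$n_up + d$n_down
    if (n == 0L) stop("design has no features", call. = FALSE)
    cls <- rep(c("background", "up", "down"),
               c(d$n_background, d$n_up, d$n_down))
    tlfc <- c(0, d$true_lfc, -d$true_lfc)[match(cls, c("background", "up",
                                                       "down"))]
    ids <- sprintf("feat_%04d", seq_len(n))
    baseline <- stats::rnorm(n, d$baseline_mean, d$baseline_sd)
    r <- d$n_replicates
    # condition c1 carries the shift; log2fc(c1 vs c2) = true_lfc
    mu <- cbind(matrix(baseline + tlfc, n, r), matrix(baseline, n, r))
    m <- mu + matrix(stats::rnorm(n * 2 * r, 0, d$noise_sd), n, 2 * r)
    if (d$missing_rate > 0)
      m[matrix(stats::runif(length(m)) < d$missing_rate, n, 2 * r)] <- NA
    samples <- c(sprintf("c1_r%d", seq_len(r)), sprintf("c2_r%d", seq_len(r)))
    colnames(m) <- samples
    design <- data.frame(sample = samples,
                         condition = rep(c("c1", "c2"), each = r),
                         stringsAsFactors = FALSE)
    ds <- omic_dataset(m, data.frame(feature_id = ids,
                                     stringsAsFactors = FALSE),
                       design, id_column = "feature_id", name = name)
    list(dataset = ds,
         truth = data.frame(feature_id = ids, class = cls, true_lfc = tlfc,
                            stringsAsFactors = FALSE))
  })
}

#' Parameters of the synthetic paired two-layer world
#'
#' Describes two omics layers (say proteomics and transcriptomics) measured
#' on the same samples, with a controllable per-feature cross-layer
#' correlation and optional group effects applied in the same or opposite
#' direction in the two layers — the latter produce "contra" features for
#' testing cross-dataset classification.
#'
#' @param n_features,n_samples matrix dimensions (`n_samples >= 3`); samples
#'   split into two equal groups `g1`/`g2`.
#' @param target_rho per-feature cross-layer correlation of the noise, in
#'   `[-1, 1]`.
#' @param n_same,n_contra numbers of features given a group effect in the
#'   same / opposite direction across layers (the rest are null).
#' @param effect_size group-mean shift, log2 units.
#' @param noise_sd within-layer noise standard deviation, log2 units.
#' @param baseline_mean,baseline_sd per-feature baseline distribution.
#' @param seed RNG seed.
#' @return a `multiomics_design` parameter list.
#' @export
multiomics_design <- function(n_features = 2000, n_samples = 50,
                              target_rho = 0.5, n_same = 0, n_contra = 0,
                              effect_size = 2, noise_sd = 1,
                              baseline_mean = 10, baseline_sd = 2, seed) {
  stopifnot(n_samples >= 3, target_rho >= -1, target_rho <= 1,
            n_same + n_contra <= n_features, noise_sd >= 0)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  structure(as.list(environment()), class = "multiomics_design")
}

#' Simulate paired two-layer multiomics data
#'
#' For each feature the two layers' values across samples are a bivariate
#' normal with correlation `target_rho` around per-layer baselines. Features
#' labelled `same` get the group effect added to group `g1` in both layers;
#' `contra` features get it added in layer 1 and subtracted in layer 2,
#' so a `g1_vs_g2` contrast flips sign between layers.
#'
#' @param d a [multiomics_design()].
#' @return list with `layer1`, `layer2` (two [omic_dataset]s sharing feature
#'   IDs and sample names) and `truth` (`feature_id`, `class` in
#'   null/same/contra, `rho`).
#' @export
simulate_multiomics <- function(d) {
  stopifnot(inherits(d, "multiomics_design"))
  .with_seed(d$seed, {
    nf <- d$n_features; ns <- d$n_samples; rho <- d$target_rho
    ids <- sprintf("feat_%04d", seq_len(nf))
    cls <- rep("null", nf)
    if (d$n_same > 0) cls[seq_len(d$n_same)] <- "same"
    if (d$n_contra > 0) cls[d$n_same + seq_len(d$n_contra)] <- "contra"
    samples <- sprintf("s%02d", seq_len(ns))
    grp <- rep(c("g1", "g2"), c(ceiling(ns / 2), floor(ns / 2)))
    z1 <- matrix(stats::rnorm(nf * ns), nf, ns)
    z2 <- rho * z1 + sqrt(1 - rho^2) * matrix(stats::rnorm(nf * ns), nf, ns)
    b1 <- stats::rnorm(nf, d$baseline_mean, d$baseline_sd)
    b2 <- stats::rnorm(nf, d$baseline_mean, d$baseline_sd)
    m1 <- b1 + d$noise_sd * z1
    m2 <- b2 + d$noise_sd * z2
    in_g1 <- grp == "g1"
    eff <- d$effect_size
    shift1 <- ifelse(cls == "null", 0, eff)
    shift2 <- ifelse(cls == "same", eff, ifelse(cls == "contra", -eff, 0))
    m1[, in_g1] <- m1[, in_g1] + shift1
    m2[, in_g1] <- m2[, in_g1] + shift2
    colnames(m1) <- colnames(m2) <- samples
    design <- data.frame(sample = samples, group = grp,
                         stringsAsFactors = FALSE)
    ann <- data.frame(feature_id = ids, stringsAsFactors = FALSE)
    list(layer1 = omic_dataset(m1, ann, design, "feature_id", name = "layer1"),
         layer2 = omic_dataset(m2, ann, design, "feature_id", name = "layer2"),
         truth = data.frame(feature_id = ids, class = cls, rho = rho,
                            stringsAsFactors = FALSE))
  })
}
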