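# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity and share no code with
# the implementation they check.

# AUC as exhaustive positive x negative pair counting, ties worth 1/2.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Product-limit estimator by direct multiplication over distinct event times
# (events processed before censorings at tied times).
km_oracle <- function(time, event) {
  event_times <- sort(unique(time[event]))
  surv <- numeric(length(event_times))
  s <- 1
  for (i in seq_along(event_times)) {
    t <- event_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = event_times, survival = surv)
}

# Monte Carlo permutation reference for the two-group log-rank test: the
# observed chi-square compared against its distribution under random
# reassignment of group labels.
log_rank_perm_oracle <- function(time, event, group, n_perm, seed) {
  obs <- survival::survdiff(survival::Surv(time, event) ~ group)$chisq
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    g <- sample(group)
    st <- survival::survdiff(survival::Surv(time, event) ~ g)$chisq
    if (st >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Brute-force maximum-margin direction for a separable 2-gene toy set:
# scans unit directions on a fine angular grid and returns the direction
# with the widest margin (midpoint bias).
max_margin_oracle <- function(x, y, n_grid = 20000L) {
  best <- list(margin = -Inf, w = NULL, b = NULL)
  for (theta in seq(0, pi, length.out = n_grid)) {
    w <- c(cos(theta), sin(theta))
    proj <- drop(x %*% w)
    for (sgn in c(1, -1)) {
      p <- sgn * proj
      margin <- (min(p[y]) - max(p[!y])) / 2
      if (margin > best$margin) {
        best <- list(margin = margin, w = sgn * w,
                     b = -(min(p[y]) + max(p[!y])) / 2)
      }
    }
  }
  best
}

# Small deterministic clinical table builder for labeling tests.
random_clinical <- function(n, seed) {
  set.seed(seed)
  status <- sample(c("yes", "no", "unknown"), n, replace = TRUE,
                   prob = c(0.4, 0.5, 0.1))
  fu <- round(runif(n, 0, 90), 1)
  ttr <- ifelse(status == "yes", round(fu * runif(n), 1), NA_real_)
  data.frame(sample_id = sprintf("P%03d", seq_len(n)),
             recurrence_status = status,
             time_to_recurrence_months = ttr,
             followup_months = fu,
             stringsAsFactors = FALSE)
}

# Small planted-signature meta-set for fast unit tests (not a preset).
small_strong_meta <- function(seed = 1L) {
  generate_meta_set(synthetic_config(
    n_family_genes = 4, planted_weights = c(1.2, 1.0),
    n_decoy_genes = 3, n_low_expression_genes = 1,
    cohort_sizes = c(train = 120, filter1 = 60, filter2 = 60, test = 100),
    hazard_log_ratio = 1.5, seed = seed))
}
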