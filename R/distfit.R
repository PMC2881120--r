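#' Threshold-binning of a degree distribution
#'
#' Variable-width binning that stabilizes heavy tails: scanning degrees
#' in ascending order, a bin is closed as soon as its accumulated count
#' reaches `min_count`; the last bin absorbs the remainder (and may fall
#' short). Bins are contiguous and cover the observed degree range. The
#' per-bin frequency is `count / (n * width)` with `n` the total node
#' count and `width` the number of integer degrees the bin spans, so a
#' frequency is comparable across distributions of different size.
#'
#' @param dist A degree count table (tibble with `degree`, `count`), as
#'   from [degree_counts()].
#' @param min_count Occupancy threshold per bin (default 10).
#' @return A tibble of class `binned_dist` with columns `k_min`, `k_max`
#'   (inclusive), `count`, `freq`, and attributes `n_nodes`,
#'   `min_count`.
#' @export
#' @examples
#' d <- tibble::tibble(degree = 1:3, count = c(5L, 4L, 8L))
#' threshold_bin(d, min_count = 9) # bins [1,2] and [3]
threshold_bin <- function(dist, min_count = 10) {
  if (min_count < 1) stop("`min_count` must be >= 1")
  if (nrow(dist) == 0) stop("empty degree distribution")
  deg <- as.integer(dist$degree)
  cnt <- as.numeric(dist$count)
  ord <- order(deg)
  deg <- deg[ord]
  cnt <- cnt[ord]
  n <- sum(cnt)
  k_min <- integer()
  k_max <- integer()
  count <- numeric()
  acc <- 0
  start <- deg[1]
  for (i in seq_along(deg)) {
    acc <- acc + cnt[i]
    if (acc >= min_count) {
      k_min <- c(k_min, start)
      k_max <- c(k_max, deg[i])
      count <- c(count, acc)
      acc <- 0
      if (i < length(deg)) start <- deg[i] + 1L
    }
  }
  if (acc > 0) { # last bin absorbs the remainder
    k_min <- c(k_min, start)
    k_max <- c(k_max, deg[length(deg)])
    count <- c(count, acc)
  }
  out <- tibble::tibble(
    k_min = k_min, k_max = k_max, count = count,
    freq = count / (n * (k_max - k_min + 1)))
  class(out) <- c("binned_dist", class(out))
  attr(out, "n_nodes") <- n
  attr(out, "min_count") <- min_count
  out
}

#' Rebin a degree distribution onto the bin grid of a target
#'
#' Sums the distribution's counts over the target's bin edges and
#' normalizes by its own total node count, so two distributions become
#' comparable frequency vectors on a common grid. Counts falling
#' outside the grid are dropped (but still count toward the
#' normalization), so probability mass beyond the target's degree range
#' depresses the in-grid frequencies and is penalized by
#' [rms_distance()] rather than silently folded into an edge bin.
#'
#' @param dist A degree count table.
#' @param bins A `binned_dist` giving the grid (typically the binned
#'   target).
#' @return A `binned_dist` on the same grid as `bins`.
#' @export
bin_on_grid <- function(dist, bins) {
  deg <- as.integer(dist$degree)
  cnt <- as.numeric(dist$count)
  n <- sum(cnt)
  if (n <= 0) stop("empty degree distribution")
  edges <- c(bins$k_min[1] - 0.5, bins$k_max + 0.5)
  idx <- findInterval(deg, edges)
  idx[deg > bins$k_max[nrow(bins)]] <- NA # beyond the grid
  count <- vapply(seq_len(nrow(bins)), function(b) {
    sum(cnt[!is.na(idx) & idx == b])
  }, numeric(1))
  out <- tibble::tibble(
    k_min = bins$k_min, k_max = bins$k_max, count = count,
    freq = count / (n * (bins$k_max - bins$k_min + 1)))
  class(out) <- c("binned_dist", class(out))
  attr(out, "n_nodes") <- n
  attr(out, "min_count") <- attr(bins, "min_count")
  out
}

#' Root-mean-square distance between binned distributions
#'
#' RMS of per-bin frequency differences. Both inputs must live on the
#' same bin grid (rebin one onto the other's grid first with
#' [bin_on_grid()]). Symmetric, zero iff the frequencies agree.
#'
#' @param a,b `binned_dist` objects on a common grid.
#' @return A nonnegative number.
#' @export
rms_distance <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$k_min != b$k_min) ||
      any(a$k_max != b$k_max)) {
    stop("mismatched bin grids; rebin onto a common grid first")
  }
  sqrt(mean((a$freq - b$freq)^2))
}

#' Two-sample rank-sum comparison of degree samples
#'
#' Two-sided Wilcoxon rank-sum test of the hypothesis that two degree
#' samples come from the same underlying distribution. Exact when both
#' samples are small and untied, otherwise the normal approximation
#' with tie correction.
#'
#' @param sample_a,sample_b Numeric vectors of node degrees.
#' @return The p-value.
#' @export
rank_sum_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be non-empty")
  }
  suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "two.sided")$p.value)
}

#' Pooled degree distribution of simulated replicate networks
#'
#' Grows `replicates` networks and pools their node degrees into one
#' count table -- the synthetic stand-in for an observed degree
#' distribution in recovery experiments.
#'
#' @param params A [growth_params()].
#' @param n_nodes Size of each grown network.
#' @param replicates Number of replicates to pool.
#' @param seed Optional master seed.
#' @return A degree count table (tibble `degree`, `count`, attribute
#'   `n_nodes` = pooled node count).
#' @export
simulate_degree_target <- function(params, n_nodes, replicates = 20,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  degs <- unlist(lapply(seq_len(replicates), function(i) {
    igraph::degree(grow_network(params, max_nodes = n_nodes))
  }))
  degree_counts(degs)
}

fit_par_names <- c("p_n", "p", "q", "p_d", "r")

# degree sample of one grown network without building an igraph object;
# candidate evaluation is the fit's hot loop
grow_degree_sample <- function(params, n_nodes, seed, iteration_cap) {
  set.seed(seed)
  res <- .grow_engine(
    params$p_n, params$p_e, params$p_d, params$p, params$q, params$r,
    cumsum(params$color_probs), params$e_matrix, params$edge_retries,
    0L, matrix(integer(), ncol = 2),
    n_nodes, -1, -1, iteration_cap, FALSE)
  if (isTRUE(res$capped)) return(NULL)
  n <- length(res$ids)
  if (n == 0) return(integer(0))
  tabulate(c(res$edges), nbins = n) # endpoint counts = degrees
}

fit_params <- function(par, edge_retries = 1000L) {
  growth_params(p_n = par[["p_n"]], p_e = 1, p_d = par[["p_d"]],
                p = par[["p"]], q = par[["q"]], r = par[["r"]],
                edge_retries = edge_retries)
}

#' Reverse-engineer growth parameters from a degree distribution
#'
#' Monte-Carlo search for the growth parameters whose networks
#' reproduce a target degree distribution. The largest event
#' probability `P_E` is fixed at 1 (only ratios of the event
#' probabilities matter for the grown structure); the remaining five
#' parameters `P_N, p, q, P_D, r` are searched in \[0, 1\] by
#' hill-climbing with Gaussian proposals (clipped to the unit cube,
#' accepted on improvement) restarted from `restarts` random points.
#'
#' Each candidate is scored by growing `replicates` networks to
#' `target_n` nodes, pooling their degrees, rebinning onto the
#' threshold-binned target grid, and taking the RMS frequency distance
#' ([rms_distance()]). Evaluations reuse one fixed set of per-replicate
#' seeds (common random numbers), so the objective is a deterministic
#' function of the parameters and the whole fit is reproducible from
#' `seed`. Candidates whose growth cannot reach `target_n` within
#' `eval_iteration_cap` iterations score `Inf`.
#'
#' @param target Degree count table of the observed network(s).
#' @param target_n Node count to grow each candidate network to.
#' @param trials Proposal trials per restart (default 200).
#' @param replicates Networks grown per evaluation (default 20).
#' @param proposal_sd Initial Gaussian proposal scale (default 0.1). The
#'   scale anneals geometrically to `proposal_sd * sigma_decay` over the
#'   trials of each restart, so the search transitions from exploration
#'   to a local descent able to follow weak gradients (the objective is
#'   nearly flat along joint rescalings of `p_n, q, p_d`).
#' @param sigma_decay Final-to-initial proposal scale ratio (default
#'   0.1).
#' @param restarts Number of random restarts (default 2).
#' @param min_count Threshold-binning occupancy (default 10).
#' @param start Optional named start vector (`p_n, p, q, p_d, r`) used
#'   for the first restart.
#' @param max_degree Optional truncation: degrees above this are dropped
#'   from the target before fitting (outlier-hub removal).
#' @param eval_iteration_cap Iteration cap per candidate growth.
#' @param seed Optional integer seed making the whole fit deterministic.
#' @return An object of class `growth_fit`: best parameters (`par`,
#'   including the fixed `p_e = 1`), `objective`, trial `history`,
#'   pooled `refit_degrees`, rank-sum `p_rank_sum` against the target,
#'   and the resolved `config`.
#' @export
monte_carlo_fit <- function(target, target_n, trials = 200,
                            replicates = 20, proposal_sd = 0.1,
                            sigma_decay = 0.1, restarts = 2,
                            min_count = 10, start = NULL,
                            max_degree = NULL, eval_iteration_cap = 1e6,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(target) == 0) stop("empty target distribution")
  if (!is.null(max_degree)) {
    target <- dplyr::filter(target, .data$degree <= max_degree)
    if (nrow(target) == 0) stop("max_degree removed the whole target")
  }
  target_bins <- threshold_bin(target, min_count = min_count)

  # all randomness drawn up front: start points, proposal noise,
  # evaluation seeds (shared by every candidate)
  starts <- matrix(runif(restarts * 5), restarts, 5,
                   dimnames = list(NULL, fit_par_names))
  if (!is.null(start)) starts[1, fit_par_names] <- start[fit_par_names]
  noise <- array(rnorm(restarts * trials * 5),
                 dim = c(restarts, trials, 5))
  sigma <- proposal_sd * sigma_decay^((seq_len(trials) - 1) /
                                        max(trials - 1, 1))
  eval_seeds <- sample.int(.Machine$integer.max - 1L, replicates)

  n_failures <- 0L
  evaluate <- function(par) {
    pars <- fit_params(par)
    degs <- integer(0)
    for (i in seq_len(replicates)) {
      d <- grow_degree_sample(pars, target_n, eval_seeds[i],
                              eval_iteration_cap)
      if (is.null(d)) { # growth could not reach target_n
        n_failures <<- n_failures + 1L
        return(list(objective = Inf, degrees = NULL))
      }
      degs <- c(degs, d)
    }
    binned <- bin_on_grid(degree_counts(degs), target_bins)
    list(objective = rms_distance(binned, target_bins), degrees = degs)
  }

  history <- vector("list", restarts)
  best_par <- NULL
  best_obj <- Inf
  for (rs in seq_len(restarts)) {
    cur <- starts[rs, ]
    cur_obj <- evaluate(cur)$objective
    h_obj <- numeric(trials + 1)
    h_obj[1] <- cur_obj
    for (t in seq_len(trials)) {
      cand <- pmin(pmax(cur + sigma[t] * noise[rs, t, ], 0), 1)
      names(cand) <- fit_par_names
      obj <- evaluate(cand)$objective
      if (obj < cur_obj) {
        cur <- cand
        cur_obj <- obj
      }
      h_obj[t + 1] <- obj
    }
    history[[rs]] <- tibble::tibble(restart = rs, trial = 0:trials,
                                    objective = h_obj)
    if (cur_obj < best_obj) {
      best_obj <- cur_obj
      best_par <- cur
    }
  }
  history <- dplyr::bind_rows(history)
  history$best <- cummin(history$objective)
  if (is.null(best_par)) {
    stop("no candidate produced a successful growth; ",
         n_failures, " failed evaluations")
  }

  final <- evaluate(best_par)
  target_degrees <- counts_to_degrees(target)
  p_rank <- rank_sum_compare(target_degrees, final$degrees)

  structure(list(
    par = c(best_par, p_e = 1),
    objective = final$objective,
    history = history,
    target_bins = target_bins,
    refit_degrees = final$degrees,
    p_rank_sum = p_rank,
    config = list(target_n = target_n, trials = trials,
                  replicates = replicates, proposal_sd = proposal_sd,
                  sigma_decay = sigma_decay,
                  restarts = restarts, min_count = min_count,
                  max_degree = max_degree, seed = seed,
                  eval_failures = n_failures)),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>\n  best parameters (P_E fixed at 1):\n")
  print(round(x$par, 4))
  cat(sprintf("  RMS objective: %.5g\n", x$objective))
  cat(sprintf("  rank-sum p (target vs refit degrees): %.4g\n",
              x$p_rank_sum))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par),
                 fixed = names(x$par) == "p_e")
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, p_rank_sum = x$p_rank_sum,
                 trials = x$config$trials, restarts = x$config$restarts,
                 replicates = x$config$replicates,
                 eval_failures = x$config$eval_failures)
}

#' @export
autoplot.growth_fit <- function(object, ...) {
  refit <- bin_on_grid(degree_counts(object$refit_degrees),
                       object$target_bins)
  mid <- (object$target_bins$k_min + object$target_bins$k_max) / 2
  df <- dplyr::bind_rows(
    tibble::tibble(k = mid, freq = object$target_bins$freq,
                   which = "target"),
    tibble::tibble(k = mid, freq = refit$freq, which = "refit"))
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$freq,
                                   colour = .data$which)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k (bin midpoint)", y = "binned p(k)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.binned_dist <- function(object, ...) {
  mid <- (object$k_min + object$k_max) / 2
  df <- tibble::tibble(k = mid, freq = object$freq)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$freq)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k (bin midpoint)", y = "binned p(k)") +
    ggplot2::theme_minimal()
}
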