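# The observer-side pipeline: selection trials -> paired-comparison choice
# matrix -> adapted maximum likelihood difference scaling (MLDS) -> CIELAB
# match -> Color Constancy Index; plus a Thurstonian synthetic observer for
# parameter-recovery testing.
#
# The scaling model: each competitor occupies a position on a 1-D perceptual
# axis and the observer holds an internal match position on the same axis.
# On each comparison the perceptual distance between each presented
# competitor and the match is contaminated by independent Gaussian noise
# (fixed SD) and the competitor with the smaller noisy distance wins - the
# canonical difference-scaling decision model, giving
# P(i beats j) = pnorm((d_j - d_i) / (sd * sqrt(2))).
#
# A second noise model is provided for comparison, in which the noise
# perturbs the competitor positions themselves and the winner is the
# competitor whose noisy position lands closest to the match. Its exact win
# probability has a closed form (with match-centered positions mu and equal
# variances, |X| < |Y| iff (Y - X)(Y + X) > 0, and Y - X, Y + X are
# independent normals), but folding the sign away leaves the likelihood
# surface with a near-flat ridge along which the match trades against its
# neighboring gaps: the scale is then not recoverable from realistic trial
# counts (see the methods vignette). The identifiable distance-noise model
# is therefore the default on both the simulation and fitting side.

COMPETITOR_ORDER <- c("T", "S2", "S1", "R", "O")

#' Simulate a synthetic observer's selection trials
#'
#' On each trial the observer compares the presented competitors to an
#' internal match on the perceptual axis and selects the one that appears
#' closest. Under the default `"distance"` noise model each competitor's
#' perceptual distance to the match receives independent Gaussian noise
#' (the difference-scaling decision model the fitting side assumes); under
#' the `"position"` model the competitor positions themselves are perturbed
#' and the one landing closest to the match is chosen. With `noise_sd = 0`
#' both rules choose the truly nearest competitor deterministically.
#'
#' @param positions Named numeric vector of true competitor positions on the
#'   perceptual axis (names are competitor ids).
#' @param match_position The observer's internal match position.
#' @param noise_sd Gaussian comparison noise SD.
#' @param n_trials Number of selection trials.
#' @param seed Integer seed; fully determines the trial list.
#' @param presentation `"pairs"` (default): competitors are shown two at a
#'   time, round-robin over all unordered pairs, so every cell of the
#'   paired-comparison matrix is directly observed. `"cycle"`: only the
#'   four adjacent pairs plus the end-anchoring (first, last) pair.
#'   `"all"`: every competitor is presented on every trial (note that with a
#'   full presentation the derived pairwise proportions collapse onto the
#'   choice shares, which constrains the scale only weakly).
#' @param noise_model `"distance"` (default) or `"position"`; see above and
#'   [fit_mlds()].
#' @return Data frame of trial records with columns `trial`, `presented`
#'   (comma-separated competitor ids) and `chosen`.
#' @export
simulate_observer <- function(positions, match_position, noise_sd = 0.1,
                              n_trials = 150, seed = 1L,
                              presentation = c("pairs", "cycle", "all"),
                              noise_model = c("distance", "position")) {
  stopifnot(!is.null(names(positions)), noise_sd >= 0, n_trials >= 1)
  presentation <- match.arg(presentation)
  noise_model <- match.arg(noise_model)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  k <- length(positions)
  ids <- names(positions)
  if (presentation == "all") {
    shown <- matrix(rep(seq_len(k), n_trials), n_trials, k, byrow = TRUE)
  } else {
    pairs <- if (presentation == "cycle") {
      rbind(cbind(seq_len(k - 1), 2:k), c(1L, k))
    } else {
      t(utils::combn(k, 2))
    }
    pick <- rep_len(seq_len(nrow(pairs)), n_trials)
    shown <- pairs[pick, , drop = FALSE]
  }
  chosen <- character(n_trials)
  presented <- character(n_trials)
  for (t in seq_len(n_trials)) {
    idx <- shown[t, ]
    eps <- stats::rnorm(length(idx), 0, noise_sd)
    d <- if (noise_model == "distance") {
      abs(positions[idx] - match_position) + eps
    } else {
      abs(positions[idx] + eps - match_position)
    }
    chosen[t] <- ids[idx[which.min(d)]]
    presented[t] <- paste(ids[idx], collapse = ",")
  }
  data.frame(trial = seq_len(n_trials), presented = presented,
             chosen = chosen, stringsAsFactors = FALSE)
}

#' Build a paired-comparison choice matrix from selection trials
#'
#' Each selection is credited as a win of the chosen competitor over every
#' other competitor presented on that trial (the standard reduction of an
#' n-alternative selection to paired comparisons). Cell (i, j) of the
#' proportion matrix is the fraction of comparisons in which i beat j;
#' uncompared pairs are `NA` and the diagonal is undefined.
#'
#' @param trials Data frame with columns `presented` (comma-separated ids)
#'   and `chosen`.
#' @param competitors Competitor ids fixing the matrix order.
#' @return Object of class `choice_matrix` with elements `prop`, `wins`,
#'   `counts` and `competitors`.
#' @export
build_choice_matrix <- function(trials, competitors = COMPETITOR_ORDER) {
  stopifnot(nrow(trials) >= 1, all(c("presented", "chosen") %in% names(trials)))
  k <- length(competitors)
  wins <- matrix(0, k, k, dimnames = list(competitors, competitors))
  for (t in seq_len(nrow(trials))) {
    pres <- strsplit(trials$presented[t], ",", fixed = TRUE)[[1]]
    ch <- trials$chosen[t]
    if (!ch %in% pres) stop("chosen competitor not among presented",
                            call. = FALSE)
    others <- setdiff(pres, ch)
    wins[ch, others] <- wins[ch, others] + 1
  }
  counts <- wins + t(wins)
  prop <- wins / counts
  prop[counts == 0] <- NA_real_
  diag(prop) <- NA_real_
  never <- competitors[colSums(counts) == 0]
  structure(list(prop = prop, wins = wins, counts = counts,
                 competitors = competitors, missing = never),
            class = "choice_matrix")
}

#' @export
print.choice_matrix <- function(x, ...) {
  cat("<choice_matrix> proportion i beats j:\n")
  print(round(x$prop, 3))
  invisible(x)
}

# P(competitor at mu_i beats competitor at mu_j), both in match-centered
# coordinates. "distance": Gaussian noise on each perceptual distance, the
# smaller noisy distance wins. "position": Gaussian noise on the positions,
# the noisy position closest to the match wins (exact closed form: with
# equal variances, |X| < |Y| iff (Y - X)(Y + X) > 0, and Y - X, Y + X are
# independent normals). Vectorized over (mu_i, mu_j).
pair_win_prob <- function(mu_i, mu_j, sd, model = "distance") {
  if (model == "distance") {
    stats::pnorm((abs(mu_j) - abs(mu_i)) / (sd * sqrt(2)))
  } else {
    a <- (mu_j - mu_i) / (sd * sqrt(2))
    b <- (mu_j + mu_i) / (sd * sqrt(2))
    stats::pnorm(a) * stats::pnorm(b) + stats::pnorm(-a) * stats::pnorm(-b)
  }
}

mlds_negloglik <- function(theta, wins, counts, sd, model) {
  k <- nrow(wins)
  pos <- c(0, cumsum(theta[2:k]))
  # the match is parameterized as a fraction of the competitor span, keeping
  # it on the competitor axis (T end = 0, over-constancy end = 1)
  m <- theta[1] * pos[k]
  nll <- 0
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      n <- counts[i, j]
      if (n == 0) next
      p <- pair_win_prob(pos[i] - m, pos[j] - m, sd, model)
      p <- min(max(p, 1e-9), 1 - 1e-9)
      nll <- nll - wins[i, j] * log(p) - wins[j, i] * log(1 - p)
    }
  }
  nll
}

#' Fit the adapted MLDS scale to a choice matrix
#'
#' Places the competitors and the observer's inferred match on a 1-D
#' perceptual axis by maximizing the Gaussian-comparison likelihood of the
#' observed win counts, under the constraints of the adapted difference
#' scaling procedure: the T position is fixed at 0, the noise SD is fixed,
#' the competitor order is preserved, and adjacent competitors are at least
#' `min_gap` apart. The match position is a free parameter of the
#' likelihood. Optimization is multistart L-BFGS-B on (match, gaps); the
#' best restart is kept; deterministic under `seed`.
#'
#' Two comparison-noise models are available. The default `"distance"`
#' model puts the Gaussian noise on each competitor's perceptual distance
#' to the match, so `P(i beats j) = pnorm((d_j - d_i) / (sd * sqrt(2)))`;
#' this likelihood identifies every gap and the match from the
#' all-pairs proportions. The `"position"` model puts the noise on the
#' competitor positions themselves (winner = noisy position closest to the
#' match); its exact likelihood carries a near-flat ridge along which the
#' match trades against its neighboring gaps, so scales fitted under it are
#' markedly less stable (kept for sensitivity analyses).
#'
#' @param cm A [build_choice_matrix()] result, ordered along the constancy
#'   axis (T first).
#' @param seed Integer seed for the restarts.
#' @param noise_sd Fixed comparison noise SD (default 0.1).
#' @param min_gap Minimum spacing between adjacent competitors
#'   (default 0.025).
#' @param n_restarts Number of multistart restarts.
#' @param noise_model `"distance"` (default) or `"position"`.
#' @return Object of class `perceptual_scale`: `positions` (named, T = 0),
#'   `match`, `noise_sd`, `logLik`, `low_confidence`.
#' @export
fit_mlds <- function(cm, seed = 1L, noise_sd = 0.1, min_gap = 0.025,
                     n_restarts = 12L,
                     noise_model = c("distance", "position")) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(cm, "choice_matrix"))
  k <- length(cm$competitors)
  n_pairs <- sum(cm$counts[upper.tri(cm$counts)] > 0)
  if (n_pairs < k) {
    warning("few compared pairs; scale may be poorly constrained",
            call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  lower <- c(0, rep(min_gap, k - 1))
  upper <- c(1, rep(1, k - 1))
  # empirical initialization: the match should sit near the most-chosen
  # competitor; gaps start at roughly the noise scale
  win_share <- rowSums(cm$wins) / max(1, sum(cm$wins))
  peak <- which.max(win_share)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      g0 <- rep(1.5 * noise_sd, k - 1)
      m0 <- (peak - 1) / (k - 1)
    } else {
      g0 <- stats::runif(k - 1, 0.05, 0.4)
      m0 <- stats::runif(1, 0, 1)
    }
    fit <- tryCatch(
      stats::optim(c(m0, g0), mlds_negloglik, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   wins = cm$wins, counts = cm$counts, sd = noise_sd,
                   model = noise_model,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("MLDS optimization failed on every restart",
                          call. = FALSE)
  pos <- c(0, cumsum(best$par[2:k]))
  names(pos) <- cm$competitors
  # low confidence when the data barely constrain the scale: near-uniform
  # observed proportions or many uncompared pairs
  props <- cm$prop[upper.tri(cm$prop)]
  low_conf <- n_pairs < k ||
    all(abs(props[is.finite(props)] - 0.5) < 0.05)
  structure(list(positions = pos, match = best$par[1] * pos[k],
                 noise_sd = noise_sd,
                 logLik = -best$value, min_gap = min_gap,
                 noise_model = noise_model,
                 low_confidence = low_conf, convergence = best$convergence),
            class = "perceptual_scale")
}

#' Log-likelihood of a perceptual configuration given a choice matrix
#'
#' Evaluates the same likelihood that [fit_mlds()] maximizes, for arbitrary
#' positions and match; used e.g. to verify maximum-likelihood dominance of
#' a fitted solution over the generating truth.
#'
#' @param cm A `choice_matrix`.
#' @param positions Named competitor positions (first must be 0).
#' @param match Match position.
#' @param noise_sd Comparison noise SD.
#' @param noise_model `"distance"` (default) or `"position"`.
#' @return Log-likelihood (scalar).
#' @export
mlds_loglik <- function(cm, positions, match, noise_sd = 0.1,
                        noise_model = c("distance", "position")) {
  noise_model <- match.arg(noise_model)
  k <- length(positions)
  span <- positions[k] - positions[1]
  theta <- c(match / span, diff(positions))
  -mlds_negloglik(theta, cm$wins, cm$counts, noise_sd, noise_model)
}

#' @export
print.perceptual_scale <- function(x, ...) {
  cat("<perceptual_scale>\n  positions:",
      paste(sprintf("%s=%.3f", names(x$positions), x$positions),
            collapse = ", "),
      sprintf("\n  match = %.3f, logLik = %.2f%s\n", x$match, x$logLik,
              if (x$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

#' Map a perceptual-scale match into CIELAB
#'
#' Locates the match between its two flanking competitors on the perceptual
#' axis and linearly interpolates between the same two competitors' Lab
#' values with the same ratio. A match beyond the first or last competitor
#' is extrapolated with the nearest segment's ratio.
#'
#' @param scale A `perceptual_scale` (positions in the order of
#'   `competitors`).
#' @param competitors A `competitor_set` supplying the Lab anchor of each
#'   competitor.
#' @return Length-3 Lab vector of the match.
#' @export
map_match_to_lab <- function(scale, competitors) {
  stopifnot(inherits(scale, "perceptual_scale"),
            inherits(competitors, "competitor_set"))
  pos <- scale$positions
  if (is.unsorted(pos)) stop("scale positions must be ordered", call. = FALSE)
  labs <- competitors$labs[names(pos), , drop = FALSE]
  m <- scale$match
  k <- length(pos)
  hi <- findInterval(m, pos, all.inside = TRUE) + 1L
  hi <- min(max(hi, 2L), k)
  lo <- hi - 1L
  r <- (m - pos[lo]) / (pos[hi] - pos[lo])
  drop(labs[lo, ] + r * (labs[hi, ] - labs[lo, ]))
}

#' Color Constancy Index
#'
#' `CCI = 100 * |T - Match| / |T - R|` with Euclidean distances in CIELAB.
#' 0 at the tristimulus match (no constancy), 100 at the reflectance match
#' (perfect constancy); values above 100 indicate over-compensation. A
#' degenerate competitor set (|T - R| = 0, e.g. under the neutral
#' illuminant) has no defined index and returns `NA` with a warning.
#'
#' @param match Length-3 Lab vector of the inferred match.
#' @param competitors A `competitor_set`.
#' @return CCI in percent.
#' @export
compute_cci <- function(match, competitors) {
  stopifnot(inherits(competitors, "competitor_set"))
  T_ <- competitors$labs["T", ]
  R_ <- competitors$labs["R", ]
  denom <- sqrt(sum((T_ - R_)^2))
  if (denom < 1e-9) {
    warning("degenerate competitor set: |T - R| = 0, CCI undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * sqrt(sum((T_ - match)^2)) / denom
}

#' MLDS parameter-recovery study
#'
#' Simulates synthetic observers whose true constancy spans the index range
#' from none to over-compensation, runs each through the full behavioral
#' pipeline (paired selection trials -> choice matrix -> MLDS fit -> CIELAB
#' interpolation -> CCI), and reports the recovery error. True competitor
#' positions sit on a uniform grid with spacing `scale_gap` so that, at the
#' fixed comparison noise of 0.1, choices are informatively stochastic.
#'
#' @param n_observers Number of synthetic observers.
#' @param cci_range True CCIs are spaced evenly over this range (percent).
#' @param n_trials Selection trials per observer.
#' @param scale_gap True gap between adjacent competitors.
#' @param noise_sd Comparison noise SD.
#' @param seed Master seed.
#' @param competitors Optional `competitor_set` used for the Lab mapping;
#'   defaults to the blue-illuminant set of the standard design.
#' @return Data frame with `true_cci`, `recovered_cci`, `abs_error`.
#' @export
mlds_recovery_study <- function(n_observers = 20, cci_range = c(0, 130),
                                n_trials = 150, scale_gap = 0.15,
                                noise_sd = 0.1, seed = 1L,
                                competitors = NULL) {
  if (is.null(competitors)) {
    ils <- make_illuminant_set(20)
    competitors <- make_competitor_set(rep(0.4, 3), ils$blue, ils$neutral)
  }
  pos <- competitor_grid() * scale_gap
  true_cci <- seq(cci_range[1], cci_range[2], length.out = n_observers)
  rec <- vapply(seq_len(n_observers), function(i) {
    m <- pos[["R"]] * true_cci[i] / 100
    tr <- simulate_observer(pos, m, noise_sd, n_trials,
                            seed = seed * 1000L + i)
    cm <- build_choice_matrix(tr)
    sc <- fit_mlds(cm, seed = seed + i)
    compute_cci(map_match_to_lab(sc, competitors), competitors)
  }, numeric(1))
  data.frame(true_cci = true_cci, recovered_cci = rec,
             abs_error = abs(rec - true_cci))
}

#' Inter- and intra-participant variability of CCI scores
#'
#' Inter-participant consistency: for each participant, the Pearson
#' correlation between their CCI vector (over conditions) and the mean CCI
#' vector of all other participants; reported per participant and averaged.
#' Intra-participant variability: each participant's coefficient of
#' variation (SD / mean) across conditions.
#'
#' @param cci A data frame with columns `participant`, `condition`, `cci`
#'   (one row per participant x condition).
#' @return List with `inter` (named vector), `inter_mean`, `intra` (named
#'   vector), `intra_mean`.
#' @export
variability_stats <- function(cci) {
  stopifnot(all(c("participant", "condition", "cci") %in% names(cci)))
  wide <- stats::xtabs(cci ~ participant + condition, data = cci)
  if (any(stats::xtabs(~ participant + condition, data = cci) != 1)) {
    stop("need exactly one CCI per participant x condition", call. = FALSE)
  }
  wide <- as.matrix(wide)
  n <- nrow(wide)
  inter <- vapply(seq_len(n), function(i) {
    others <- colMeans(wide[-i, , drop = FALSE])
    stats::cor(wide[i, ], others)
  }, numeric(1))
  names(inter) <- rownames(wide)
  intra <- apply(wide, 1, function(x) stats::sd(x) / mean(x))
  list(inter = inter, inter_mean = mean(inter),
       intra = intra, intra_mean = mean(intra))
}
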