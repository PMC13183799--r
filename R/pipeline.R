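# End-to-end experiment orchestration: factorial CCI tables over
# {scene palette x mechanism x illuminant x agent}, baseline-referenced
# differences, and model-human agreement reports.
#
# Agents come in two families. Image-computable agents (the oracle, the
# zero-constancy tristimulus reference, trained reflectance networks, and
# classical white-balance algorithms) are scored through the masked-average
# / projection / interpolation pipeline. Synthetic observers are scored
# through the behavioral pipeline; by default their matches are sampled
# directly on the constancy axis (cheap), with an optional full
# trials -> choice matrix -> MLDS route.

#' Construct an experiment configuration
#'
#' @param seed Master seed; fully determines every downstream artifact.
#' @param palettes Scene palettes to include (`"indoor"`, `"outdoor"`).
#' @param mechanisms Mechanisms for experiment 1.
#' @param axis_offset Illuminant chromatic step in Lab units.
#' @param size Image side in pixels.
#' @param n_locations Target placements per scene.
#' @param target_reflectance Achromatic target reflectance.
#' @param agents List of agent specifications (see [agent_oracle()] and
#'   friends).
#' @param observers Observer-pool configuration from [observer_pool()], or
#'   `NULL` for no observers.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              palettes = c("indoor", "outdoor"),
                              mechanisms = SCENE_MECHANISMS,
                              axis_offset = 20, size = 64L,
                              n_locations = 3L,
                              target_reflectance = rep(0.4, 3),
                              agents = list(agent_oracle()),
                              observers = NULL) {
  structure(list(seed = as.integer(seed), palettes = palettes,
                 mechanisms = mechanisms, axis_offset = axis_offset,
                 size = as.integer(size), n_locations = as.integer(n_locations),
                 target_reflectance = target_reflectance,
                 agents = agents, observers = observers),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields of [experiment_config()] may be specified in a YAML file;
#' agents and observers are constructed from their names/parameters.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("seed", "palettes", "mechanisms",
                                  "axis_offset", "size", "n_locations",
                                  "target_reflectance"))]
  agents <- lapply(y$agents %||% list("oracle"), function(a) {
    if (is.character(a)) {
      switch(a, oracle = agent_oracle(), tristimulus = agent_tristimulus(),
             agent_classical(a))
    } else {
      do.call(agent_classical, a)
    }
  })
  obs <- if (!is.null(y$observers)) {
    o <- y$observers
    # YAML 1.1 parses a bare key `n` as a boolean; map it back
    names(o)[names(o) %in% c("FALSE", "no")] <- "n"
    do.call(observer_pool, o)
  }
  do.call(experiment_config, c(args, list(agents = agents, observers = obs)))
}

#' Agent specifications
#'
#' * `agent_oracle()` - predicts the ground-truth reflectance Lab map
#'   (perfect constancy; CCI 100 by construction).
#' * `agent_tristimulus()` - predicts the raw image's Lab values (zero
#'   constancy; CCI near 0 under chromatic illuminants).
#' * `agent_net()` - a trained [reflectance_net].
#' * `agent_classical()` - a classical illuminant-estimation method scored
#'   through white balancing; `method` is one of `"gray_world"`,
#'   `"white_patch"`, `"shades_of_gray"`, `"gray_edge"`,
#'   `"weighted_gray_edge"`, and `params` are forwarded to it.
#'
#' @param model A trained `reflectance_net`.
#' @param name Agent display name.
#' @param method Classical method name.
#' @param params Parameter list for the classical method.
#' @return An `agent_spec`.
#' @export
agent_oracle <- function(name = "oracle") {
  structure(list(name = name, type = "oracle"), class = "agent_spec")
}

#' @rdname agent_oracle
#' @export
agent_tristimulus <- function(name = "tristimulus") {
  structure(list(name = name, type = "tristimulus"), class = "agent_spec")
}

#' @rdname agent_oracle
#' @export
agent_net <- function(model, name = "reflectance_net") {
  stopifnot(inherits(model, "reflectance_net"))
  structure(list(name = name, type = "net", model = model),
            class = "agent_spec")
}

#' @rdname agent_oracle
#' @export
agent_classical <- function(method, name = method, params = list()) {
  fns <- c("gray_world", "white_patch", "shades_of_gray", "gray_edge",
           "weighted_gray_edge")
  if (!method %in% fns) stop("unknown classical method: ", method,
                             call. = FALSE)
  structure(list(name = name, type = "classical", method = method,
                 params = params),
            class = "agent_spec")
}

#' Configure a synthetic observer pool
#'
#' The pool emulates the study's human observers: each participant has a
#' per-participant baseline constancy level, mechanism-specific drops, and
#' condition-level noise. Defaults follow the reported human pattern: high
#' baseline constancy and the characteristic ordering of mechanism effects
#' (spatial-mean reflectance changes most damaging, maximum flux least).
#'
#' @param n Participants per scene palette.
#' @param baseline_mean,baseline_sd Population mean and SD of per-participant
#'   baseline CCI (percent).
#' @param mechanism_effects Named mean CCI drops per silencing mechanism
#'   (percentage points, negative = worse).
#' @param direction_effects Named mean CCI drops for experiment 2, by
#'   illuminant-surround `Direction`.
#' @param cell_sd SD of condition-level noise (percentage points).
#' @param method `"direct"` (sample the match on the constancy axis) or
#'   `"mlds"` (simulate trials and refit the full scaling pipeline).
#' @param trials_per_illuminant Selection trials per illuminant for the
#'   `"mlds"` route.
#' @param scale_gap True perceptual gap between adjacent competitors for the
#'   `"mlds"` route (in noise-SD units of 0.1 this controls choice
#'   stochasticity).
#' @return Object of class `observer_pool`.
#' @export
observer_pool <- function(n = 10L, baseline_mean = 85, baseline_sd = 8,
                          mechanism_effects = c(local_surround = -19.1,
                                                maximum_flux = -4.7,
                                                spatial_mean_add = -18.4,
                                                spatial_mean_change = -74.3),
                          direction_effects = c(Neighboring = -1,
                                                Opposing = -8),
                          cell_sd = 8,
                          method = c("direct", "mlds"),
                          trials_per_illuminant = 150L,
                          scale_gap = 0.15) {
  method <- match.arg(method)
  structure(list(n = as.integer(n), baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 mechanism_effects = mechanism_effects,
                 direction_effects = direction_effects,
                 cell_sd = cell_sd, method = method,
                 trials_per_illuminant = as.integer(trials_per_illuminant),
                 scale_gap = scale_gap),
            class = "observer_pool")
}

# Predicted Lab maps for one agent on a list of dataset records.
agent_lab_maps <- function(agent, records, neutral, white = white_d65(),
                           primaries = srgb_primaries()) {
  lapply(records, function(rec) {
    sc <- rec$scene
    dims <- dim(sc$rgb)
    if (agent$type == "oracle") {
      refl_lit <- sc$reflectance
      for (k in 1:3) refl_lit[, , k] <- refl_lit[, , k] * neutral$gain[k]
      array(linear_rgb_to_lab(matrix(refl_lit, ncol = 3), white, primaries),
            dim = dims)
    } else if (agent$type == "tristimulus") {
      array(linear_rgb_to_lab(matrix(sc$rgb, ncol = 3), white, primaries),
            dim = dims)
    } else if (agent$type == "net") {
      predict_reflectance(agent$model, sc$rgb)
    } else if (agent$type == "classical") {
      est <- do.call(agent$method, c(list(sc$rgb), agent$params))
      img <- if (est$degenerate) sc$rgb else white_balance(sc$rgb, est)
      array(linear_rgb_to_lab(matrix(img, ncol = 3), white, primaries),
            dim = dims)
    } else {
      stop("unknown agent type: ", agent$type, call. = FALSE)
    }
  })
}

# Score one agent in one (mechanism, illuminant) cell of a dataset.
score_agent_cell <- function(agent, records, comp_set, neutral) {
  maps <- agent_lab_maps(agent, records, neutral)
  masks <- lapply(records, function(r) r$scene$mask)
  comp_names <- rownames(comp_set$labs)
  preds <- lapply(seq_along(comp_names), function(ci) {
    in_cell <- vapply(records, function(r) r$competitor == comp_names[ci],
                      logical(1))
    average_masked(maps[in_cell], masks[in_cell], ci)
  })
  names(preds) <- comp_names
  match <- infer_model_match(preds, comp_set)
  model_cci(match, comp_set)
}

# Sample or measure one observer's CCI in one condition cell.
observer_cell_cci <- function(pool, base_cci, effect, comp_set, seed) {
  target <- base_cci + effect
  if (pool$method == "direct") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    return(target + stats::rnorm(1, 0, pool$cell_sd))
  }
  # full behavioral route: internal match on the perceptual axis, noisy
  # selection trials, choice matrix, MLDS, Lab interpolation, CCI
  positions <- competitor_grid() * pool$scale_gap
  m_true <- (target / 100) * positions[["R"]]
  trials <- simulate_observer(positions, m_true, noise_sd = 0.1,
                              n_trials = pool$trials_per_illuminant,
                              seed = seed)
  cm <- build_choice_matrix(trials)
  scale <- fit_mlds(cm, seed = seed)
  compute_cci(map_match_to_lab(scale, comp_set), comp_set)
}

chromatic_illums <- function(illum_set) {
  illum_set[vapply(illum_set, function(i) is.finite(i$hue), logical(1))]
}

#' Run experiment 1: color constancy mechanisms
#'
#' Full factorial over {scene palette x mechanism x chromatic illuminant x
#' agent}: renders the competitor dataset for each cell, scores every
#' image-computable agent through the model-match pipeline and every
#' synthetic observer through the behavioral pipeline, and derives
#' baseline-referenced ΔCCI and model-human agreement.
#'
#' @param config An [experiment_config()].
#' @return List of class `experiment_result`: `cci` (record table),
#'   `delta` (ΔCCI vs the baseline condition on matched keys),
#'   `agreement` (per image-computable agent, when observers are present),
#'   `config`.
#' @export
run_experiment1 <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  illum_set <- make_illuminant_set(config$axis_offset)
  neutral <- illum_set$neutral
  chrom <- chromatic_illums(illum_set)
  rows <- list()
  ri <- 0L
  add_row <- function(agent, type, scene, mech, illum, cci) {
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(agent = agent, agent_type = type,
                              scene = scene, mechanism = mech,
                              surround = NA_character_, illuminant = illum,
                              cci = cci, stringsAsFactors = FALSE)
  }

  for (pal in config$palettes) {
    ds <- generate_experiment_dataset(
      illum_set, mechanisms = config$mechanisms, palette = pal,
      n_locations = config$n_locations,
      target_reflectance = config$target_reflectance,
      size = config$size, seed = config$seed)
    for (mech in config$mechanisms) {
      for (il in names(chrom)) {
        idx <- ds$manifest$mechanism == mech & ds$manifest$illuminant == il
        records <- ds$records[idx]
        cs <- ds$competitor_sets[[il]]
        for (agent in config$agents) {
          add_row(agent$name, agent$type, pal, mech, il,
                  score_agent_cell(agent, records, cs, neutral))
        }
      }
    }
    if (!is.null(config$observers)) {
      pool <- config$observers
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(config$seed + match(pal, config$palettes))
      baselines <- stats::rnorm(pool$n, pool$baseline_mean, pool$baseline_sd)
      cell_seeds <- matrix(
        sample.int(.Machine$integer.max %/% 2,
                   pool$n * length(config$mechanisms) * length(chrom)),
        nrow = pool$n)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      for (oi in seq_len(pool$n)) {
        ci <- 0L
        for (mech in config$mechanisms) {
          eff <- if (mech == "baseline") 0 else
            pool$mechanism_effects[[mech]] %||% 0
          for (il in names(chrom)) {
            ci <- ci + 1L
            cci <- observer_cell_cci(pool, baselines[oi], eff,
                                     ds$competitor_sets[[il]],
                                     cell_seeds[oi, ci])
            add_row(sprintf("%s_obs%02d", pal, oi), "observer", pal,
                    mech, il, cci)
          }
        }
      }
    }
  }

  cci_tab <- do.call(rbind, rows)
  base <- cci_tab[cci_tab$mechanism == "baseline",
                  setdiff(names(cci_tab), "mechanism")]
  cond <- cci_tab[cci_tab$mechanism != "baseline", ]
  delta <- NULL
  if (nrow(cond) && nrow(base)) {
    delta <- do.call(rbind, lapply(split(cond, cond$mechanism), function(d) {
      dd <- delta_cci(d[setdiff(names(d), "mechanism")], base)
      dd$mechanism <- d$mechanism[1]
      dd
    }))
    rownames(delta) <- NULL
  }
  agreement <- compute_agreements(cci_tab)
  structure(list(cci = cci_tab, delta = delta, agreement = agreement,
                 config = config),
            class = "experiment_result")
}

# Agreement reports for each image-computable agent against the observer
# pool, over (scene, mechanism, surround, illuminant) condition cells.
# Participants only score their own scene, so the human mean is taken per
# condition over the participants who completed it, and the leave-one-out
# agreement is computed within each participant's own condition subset.
compute_agreements <- function(cci_tab) {
  obs <- cci_tab[cci_tab$agent_type == "observer", ]
  mods <- cci_tab[cci_tab$agent_type != "observer", ]
  if (!nrow(obs) || !nrow(mods)) return(NULL)
  key <- function(d) paste(d$scene, d$mechanism, d$surround, d$illuminant,
                           sep = "|")
  obs$cond <- key(obs)
  human_mean_of <- function(conds, exclude = NULL) {
    d <- obs[!(obs$agent %in% exclude), ]
    vapply(conds, function(cn) mean(d$cci[d$cond == cn]), numeric(1))
  }
  parts <- unique(obs$agent)
  loo_per <- vapply(parts, function(p) {
    mine <- obs[obs$agent == p, ]
    others <- human_mean_of(mine$cond, exclude = p)
    if (any(!is.finite(others)) || length(mine$cond) < 2) return(NA_real_)
    lin_ccc(mine$cci, others)
  }, numeric(1))
  loo <- mean(loo_per, na.rm = TRUE)

  out <- list()
  for (nm in unique(mods$agent)) {
    m <- mods[mods$agent == nm, ]
    mk <- key(m)
    conds <- intersect(unique(mk), unique(obs$cond))
    if (length(conds) < 3) next
    model_vec <- m$cci[match(conds, mk)]
    hm <- human_mean_of(conds)
    diffs <- model_vec - hm
    ccc <- lin_ccc(model_vec, hm)
    out[[nm]] <- structure(
      list(grouping = "all",
           accuracy = stats::cor(model_vec, hm),
           bias = mean(diffs),
           normalized_error = sqrt(mean(diffs^2)) / stats::sd(hm),
           ccc = ccc, loo = loo,
           nccc = if (abs(loo) > 1e-12) ccc / loo else NA_real_),
      class = "agreement_report")
  }
  if (length(out)) out else NULL
}

#' Run experiment 2: local surround color x illumination
#'
#' Factorial over {scene palette x surround color x {baseline, silenced} x
#' chromatic illuminant x agent}. Every scene places a colored leaf under
#' the targets; in the silenced condition the leaf's rendered color is held
#' fixed across illuminants. Each chromatic cell carries a `direction`
#' label (Neighboring/Opposing) from [classify_direction()].
#'
#' @param config An [experiment_config()] (its `mechanisms` field is
#'   ignored; the two conditions are fixed by the design).
#' @param surrounds Surround set from [make_surround_color_set()].
#' @return List of class `experiment_result` with `cci` (including
#'   `surround` and `direction` columns), `delta` (silenced minus
#'   per-surround baseline), `agreement`, `config`.
#' @export
run_experiment2 <- function(config = experiment_config(),
                            surrounds = make_surround_color_set()) {
  stopifnot(inherits(config, "experiment_config"))
  illum_set <- make_illuminant_set(config$axis_offset)
  neutral <- illum_set$neutral
  chrom <- chromatic_illums(illum_set)
  rows <- list()
  ri <- 0L
  add_row <- function(agent, type, scene, mech, surround, illum, direction,
                      cci) {
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(agent = agent, agent_type = type,
                              scene = scene, mechanism = mech,
                              surround = surround, illuminant = illum,
                              direction = direction, cci = cci,
                              stringsAsFactors = FALSE)
  }

  for (pal in config$palettes) {
    for (snm in names(surrounds)) {
      sur <- surrounds[[snm]]
      ds <- generate_experiment_dataset(
        illum_set, mechanisms = c("baseline", "local_surround"),
        palette = pal, n_locations = config$n_locations,
        target_reflectance = config$target_reflectance,
        surround = sur, size = config$size, seed = config$seed)
      for (mech in c("baseline", "local_surround")) {
        for (il in names(chrom)) {
          dir <- classify_direction(chrom[[il]], sur$hue)
          idx <- ds$manifest$mechanism == mech & ds$manifest$illuminant == il
          records <- ds$records[idx]
          cs <- ds$competitor_sets[[il]]
          for (agent in config$agents) {
            add_row(agent$name, agent$type, pal, mech, snm, il, dir,
                    score_agent_cell(agent, records, cs, neutral))
          }
        }
      }
      if (!is.null(config$observers)) {
        pool <- config$observers
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        set.seed(config$seed + 131 * match(snm, names(surrounds)) +
                   match(pal, config$palettes))
        baselines <- stats::rnorm(pool$n, pool$baseline_mean,
                                  pool$baseline_sd)
        cell_seeds <- matrix(
          sample.int(.Machine$integer.max %/% 2, pool$n * 2 * length(chrom)),
          nrow = pool$n)
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        for (oi in seq_len(pool$n)) {
          ci <- 0L
          for (mech in c("baseline", "local_surround")) {
            for (il in names(chrom)) {
              ci <- ci + 1L
              dir <- classify_direction(chrom[[il]], sur$hue)
              eff <- if (mech == "baseline") 0 else
                pool$direction_effects[[dir]] %||% 0
              cci <- observer_cell_cci(pool, baselines[oi], eff,
                                       ds$competitor_sets[[il]],
                                       cell_seeds[oi, ci])
              add_row(sprintf("%s_obs%02d", pal, oi), "observer", pal,
                      mech, snm, il, dir, cci)
            }
          }
        }
      }
    }
  }

  cci_tab <- do.call(rbind, rows)
  base <- cci_tab[cci_tab$mechanism == "baseline",
                  setdiff(names(cci_tab), "mechanism")]
  cond <- cci_tab[cci_tab$mechanism == "local_surround", ]
  delta <- delta_cci(cond[setdiff(names(cond), "mechanism")], base)
  agreement <- compute_agreements(cci_tab)
  structure(list(cci = cci_tab, delta = delta, agreement = agreement,
                 config = config),
            class = "experiment_result")
}

#' Summarize experiment results
#'
#' Per-mechanism mean ΔCCI ranking for each agent (most damaging mechanism
#' first), plus the agreement reports when observers were simulated.
#'
#' @param result An `experiment_result`.
#' @return List of class `cc_report` with `delta_summary` (data frame) and
#'   `agreement`.
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  d <- result$delta
  summ <- NULL
  if (!is.null(d) && nrow(d)) {
    grp_cols <- intersect(c("agent", "mechanism", "surround"), names(d))
    grp_cols <- grp_cols[vapply(grp_cols, function(cn)
      length(unique(d[[cn]])) > 1 || cn %in% c("agent", "mechanism"),
      logical(1))]
    agg <- stats::aggregate(d["delta_cci"],
                            by = d[intersect(grp_cols, names(d))],
                            FUN = mean)
    agg <- agg[order(agg$agent, agg$delta_cci), ]
    rownames(agg) <- NULL
    summ <- agg
  }
  structure(list(delta_summary = summ, agreement = result$agreement,
                 seed = result$config$seed),
            class = "cc_report")
}

#' @export
print.cc_report <- function(x, ...) {
  cat("Mean ΔCCI by agent and mechanism (most damaging first):\n")
  if (!is.null(x$delta_summary)) print(x$delta_summary, digits = 4)
  if (!is.null(x$agreement)) {
    cat("\nModel-human agreement:\n")
    for (nm in names(x$agreement)) {
      cat(sprintf("  %-18s", nm)); print(x$agreement[[nm]])
    }
  }
  invisible(x)
}
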