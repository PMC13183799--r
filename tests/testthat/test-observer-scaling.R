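test_that("choice matrices credit selections as pairwise wins", {
  # deterministic always-R chooser over full presentations
  tr <- data.frame(trial = 1:6, presented = "T,S2,S1,R,O", chosen = "R")
  cm <- build_choice_matrix(tr)
  expect_true(all(cm$prop["R", c("T", "S2", "S1", "O")] == 1))
  expect_true(all(cm$prop[c("T", "S2", "S1", "O"), "R"] == 0))
  # a single selection of S1 among all five
  one <- build_choice_matrix(data.frame(trial = 1, presented = "T,S2,S1,R,O",
                                        chosen = "S1"))
  expect_true(all(one$wins["S1", c("T", "S2", "R", "O")] == 1))
  expect_equal(sum(one$counts) / 2, 4)
  expect_error(build_choice_matrix(
    data.frame(trial = 1, presented = "T,S2", chosen = "R")),
    "not among presented")
})

test_that("never-presented competitors are flagged missing", {
  tr <- data.frame(trial = 1:4, presented = "T,S2", chosen = "S2")
  cm <- build_choice_matrix(tr)
  expect_setequal(cm$missing, c("S1", "R", "O"))
  expect_true(all(is.na(cm$prop["S1", ])))
})

test_that("the complement identity holds on simulated trial sets", {
  pos <- competitor_grid() * 0.15
  for (s in 1:5) {
    tr <- simulate_observer(pos, 0.3, 0.1, 120, seed = s)
    cm <- build_choice_matrix(tr)
    pair_sum <- cm$prop + t(cm$prop)
    ok <- cm$counts > 0
    expect_true(all(abs(pair_sum[ok] - 1) < 1e-12))
  }
})

test_that("the simulated observer is deterministic and noiseless in the limit", {
  pos <- competitor_grid() * 0.15
  expect_identical(simulate_observer(pos, 0.2, 0.1, 60, seed = 3),
                   simulate_observer(pos, 0.2, 0.1, 60, seed = 3))
  # zero noise: the nearer presented competitor wins every pair trial
  tr <- simulate_observer(pos, 0.31, 0, 100, seed = 1)
  for (t in seq_len(nrow(tr))) {
    pres <- strsplit(tr$presented[t], ",")[[1]]
    nearest <- pres[which.min(abs(pos[pres] - 0.31))]
    expect_identical(tr$chosen[t], nearest)
  }
})

test_that("competitors symmetric about the match are chosen equally often", {
  pos <- c(A = -0.1, B = 0.1)
  tr <- simulate_observer(pos, 0, 0.1, 4000, seed = 9)
  p <- mean(tr$chosen == "A")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("MLDS recovers known scales from simulated choice data", {
  pos <- competitor_grid() * 0.15
  cs <- test_competitors("blue")
  for (case in list(list(m = 0.10, seed = 21), list(m = 0.40, seed = 22))) {
    tr <- simulate_observer(pos, case$m, 0.1, 2000, seed = case$seed)
    cm <- build_choice_matrix(tr)
    sc <- fit_mlds(cm, seed = case$seed)
    # the match and the ordering/scale are recovered; individual gaps carry
    # the residual uncertainty of the comparison design
    expect_lt(abs(sc$match - case$m), 0.06)
    expect_false(is.unsorted(sc$positions))
    expect_lt(max(abs(sc$positions - pos)), 0.2)
    cci_true <- 100 * case$m / pos[["R"]]
    cci_rec <- compute_cci(map_match_to_lab(sc, cs), cs)
    expect_lt(abs(cci_rec - cci_true), 15)
    # maximum-likelihood dominance over the generating truth
    expect_gte(sc$logLik, mlds_loglik(cm, pos, case$m) - 1e-6)
  }
})

test_that("an always-R chooser puts the match at or beyond R", {
  tr <- data.frame(trial = 1:200,
                   presented = rep(c("T,R", "S2,R", "S1,R", "O,R", "T,S2",
                                     "T,S1", "T,O", "S2,S1", "S2,O", "S1,O"),
                                   20),
                   chosen = rep(c(rep("R", 4), "S2", "S1", "O", "S1", "O",
                                  "O"), 20))
  cm <- build_choice_matrix(tr)
  sc <- fit_mlds(cm, seed = 1)
  expect_gte(sc$match, sc$positions[["R"]] - 1e-6)
})

test_that("a non-identifiable all-tied matrix is flagged low confidence", {
  pairs <- c("T,S2", "S2,S1", "S1,R", "R,O")
  tr <- data.frame(trial = 1:8,
                   presented = rep(pairs, 2),
                   chosen = c("T", "S2", "S1", "R", "S2", "S1", "R", "O"))
  cm <- build_choice_matrix(tr)
  expect_warning(sc <- fit_mlds(cm, seed = 1), "poorly constrained")
  expect_true(sc$low_confidence)
})

test_that("matches map into Lab by flanking-segment interpolation", {
  cs <- test_competitors("blue")
  pos <- competitor_grid() * 0.15
  mk_scale <- function(m) {
    structure(list(positions = pos, match = m, noise_sd = 0.1),
              class = "perceptual_scale")
  }
  expect_equal(map_match_to_lab(mk_scale(pos[["S1"]]), cs),
               cs$labs["S1", ], ignore_attr = TRUE)
  mid <- map_match_to_lab(mk_scale((pos[["S1"]] + pos[["S2"]]) / 2), cs)
  expect_equal(mid, (cs$labs["S1", ] + cs$labs["S2", ]) / 2,
               ignore_attr = TRUE)
  r <- 0.37
  m <- pos[["T"]] + r * (pos[["S2"]] - pos[["T"]])
  expect_equal(map_match_to_lab(mk_scale(m), cs),
               cs$labs["T", ] + r * (cs$labs["S2", ] - cs$labs["T", ]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the constancy index anchors at its definitional values", {
  cs <- test_competitors("blue")
  expect_equal(compute_cci(cs$labs["R", ], cs), 100)
  expect_equal(compute_cci(cs$labs["T", ], cs), 0)
  expect_equal(compute_cci((cs$labs["R", ] + cs$labs["T", ]) / 2, cs), 50)
  expect_equal(compute_cci(cs$labs["O", ], cs), 400 / 3, tolerance = 1e-9)
  ils <- test_illuminants(20)
  degen <- make_competitor_set(rep(0.4, 3), ils$neutral, ils$neutral)
  expect_warning(v <- compute_cci(c(70, 0, 0), degen), "degenerate")
  expect_true(is.na(v))
})

test_that("the index is invariant to similarity transforms of Lab", {
  cs <- test_competitors("green")
  match <- cs$labs["S1", ] + 0.4 * (cs$labs["R", ] - cs$labs["S1", ])
  base <- compute_cci(match, cs)
  # rotate, scale and translate all points jointly
  set.seed(2)
  ang <- 0.7
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  tf <- function(x) drop(2.5 * Rz %*% x + c(10, -5, 3))
  cs2 <- cs
  cs2$labs <- t(apply(cs$labs, 1, tf))
  expect_equal(compute_cci(tf(match), cs2), base, tolerance = 1e-9)
})

test_that("variability statistics match their definitions", {
  conds <- paste0("c", 1:4)
  ident <- do.call(rbind, lapply(1:3, function(p)
    data.frame(participant = paste0("p", p), condition = conds,
               cci = c(80, 60, 90, 40))))
  v <- variability_stats(ident)
  expect_equal(unname(v$inter), rep(1, 3))
  expect_equal(v$inter_mean, 1)
  flat <- data.frame(participant = "p1", condition = conds, cci = 70)
  mixed <- rbind(flat,
                 data.frame(participant = "p2", condition = conds,
                            cci = c(50, 60, 70, 80)))
  # p1 has zero variance, so their inter-participant correlation is
  # undefined (warned); the CV is still well defined
  v2 <- suppressWarnings(variability_stats(mixed))
  expect_equal(unname(v2$intra["p1"]), 0)
  # an anti-correlated participant has negative consistency
  anti <- rbind(ident,
                data.frame(participant = "p4", condition = conds,
                           cci = c(40, 90, 30, 95)))
  v3 <- variability_stats(anti)
  expect_lt(v3$inter[["p4"]], 0)
  expect_equal(v3$inter[["p4"]],
               cor(c(40, 90, 30, 95), c(80, 60, 90, 40)))
})
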