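single_terminal_cfg <- function(term = c(0, 0, 20)) {
  growth_config(
    perfusion_region = list(type = "box", lower = term - 0.01,
                            upper = term + 0.01),
    n_terminals = 1L, terminal_flows = 0.5,
    inlet_position = c(0, 0, 0), rng_seed = 5L)
}

test_that("one terminal gives a single straight Poiseuille segment", {
  cfg <- single_terminal_cfg()
  tr <- grow_tree(cfg)
  expect_length(tr$centerlines, 1L)
  cl <- tr$centerlines[[1]]
  # straight: every node on the inlet-terminal chord
  chord <- (cl$nodes[, 3]) / cl$nodes[nrow(cl$nodes), 3]
  expect_lt(max(abs(cl$nodes[, 1:2])), 0.05)
  # radius from Poiseuille at the prescribed pressure drop:
  # dP = 8 mu L Q / (pi r^4)  ->  r = (8 mu L Q / (pi dP))^(1/4)
  L <- cl$length * 1e-3
  Q <- 0.5 * 1e-6
  r_exp <- (8 * cfg$viscosity * L * Q / (pi * cfg$pressure_drop))^(1 / 4) * 1e3
  expect_equal(cl$radii[1], r_exp, tolerance = 0.02)
})

test_that("mirror-symmetric terminals put the bifurcation on the symmetry plane", {
  cfg <- growth_config(
    perfusion_region = list(type = "box", lower = c(-10, -1, 19),
                            upper = c(10, 1, 21)),
    n_terminals = 2L, terminal_flows = 0.4,
    inlet_position = c(0, 0, 0), target_inlet_radius = 2, rng_seed = 1L)
  tr <- grow_tree(cfg)
  # force exact mirror terminals by brute-force oracle instead: check the
  # optimizer's bifurcation against a grid search of the volume objective
  g <- attr(tr, "growth")
  # identify the bifurcation: end of the root centerline
  root <- tr$centerlines[[tr$inlet]]
  bif <- root$nodes[nrow(root$nodes), ]
  kids <- which(tr$parent == tr$inlet)
  t1 <- tr$centerlines[[kids[1]]]
  t2 <- tr$centerlines[[kids[2]]]
  term1 <- t1$nodes[nrow(t1$nodes), ]
  term2 <- t2$nodes[nrow(t2$nodes), ]
  q1 <- g$flow[kids[1]]; q2 <- g$flow[kids[2]]
  r_root <- root$radii[1]
  # brute-force grid around the found optimum
  vol_at <- function(x) oracle_bif_volume(x, c(0, 0, 0), term1, term2,
                                          q1, q2, r_root)
  v0 <- vol_at(bif)
  for (k in 1:40) {
    cand <- bif + runif(3, -0.25, 0.25)
    expect_gte(vol_at(cand), v0 - 1e-3 * v0)
  }
})

test_that("every bifurcation satisfies the power law and matter preservation", {
  tr <- cached_calix_tree()
  g <- attr(tr, "growth")
  gamma <- g$config$bifurcation_exponent
  for (i in seq_along(tr$centerlines)) {
    kids <- which(!is.na(tr$parent) & tr$parent == i)
    if (!length(kids)) next
    # matter preservation: flow in = sum of child flows
    expect_equal(g$flow[i], sum(g$flow[kids]), tolerance = 1e-10)
    # bifurcation law r_p^gamma = sum r_c^gamma
    rp <- tr$centerlines[[i]]$radii[length(tr$centerlines[[i]]$radii)]
    rc <- vapply(kids, function(k) tr$centerlines[[k]]$radii[1], 0)
    expect_equal(rp^gamma, sum(rc^gamma), tolerance = 1e-8 * rp^gamma)
  }
})

test_that("CALIX-like tree reproduces the printed diameter range", {
  tr <- cached_calix_tree()
  expect_equal(length(tree_leaves(tr)), 14L)
  outlet_d <- vapply(tree_leaves(tr), function(i) {
    r <- tr$centerlines[[i]]$radii
    2 * r[length(r)]
  }, 0)
  inlet_d <- 2 * tr$centerlines[[tr$inlet]]$radii[1]
  expect_true(all(outlet_d >= 1.5))
  expect_equal(inlet_d, 5, tolerance = 0.05)
})

test_that("remodelled trees keep endpoints and radii exactly", {
  tr0 <- grow_tree(single_terminal_cfg())
  tr1 <- remodel_curved(tr0, amplitude = 1, rng_seed = 3)
  cl0 <- tr0$centerlines[[1]]; cl1 <- tr1$centerlines[[1]]
  n0 <- nrow(cl0$nodes); n1 <- nrow(cl1$nodes)
  expect_equal(cl1$nodes[1, ], cl0$nodes[1, ], tolerance = 1e-12)
  expect_equal(cl1$nodes[n1, ], cl0$nodes[n0, ], tolerance = 1e-12)
  expect_equal(cl1$radii[c(1, n1)], cl0$radii[c(1, n0)], tolerance = 1e-12)
  # amplitude 0 is the identity
  tr2 <- remodel_curved(tr0, amplitude = 0, rng_seed = 3)
  expect_equal(max(abs(tr2$centerlines[[1]]$nodes[, 1:2])),
               max(abs(cl0$nodes[, 1:2])), tolerance = 1e-9)
  # chord deviation bounded by 3 x amplitude (two modes of <= 1.5x each)
  s <- seq(0, 1, length.out = 200)
  P <- eval_position(cl1, s)
  chord0 <- cl0$nodes[1, ]; chordv <- cl0$nodes[n0, ] - chord0
  tpar <- as.matrix((sweep(P, 2, chord0)) %*% chordv) / sum(chordv^2)
  foot <- outer(as.numeric(tpar), chordv) +
    matrix(chord0, length(s), 3, byrow = TRUE)
  expect_lte(max(sqrt(rowSums((P - foot)^2))), 3 * 1)
})
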