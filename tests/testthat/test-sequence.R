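test_that("conventional acquisition uses one TR per phase-encode line", {
  p <- sequence_params(TE = 5, TR = 20, FA = 25, FOV = c(128, 128),
                       matrix_size = c(64, 64), VENC = 100, n_dummy = 0L)
  sch <- sequence_schedule(p)
  one <- sch[sch$venc_axis == "SS" & sch$polarity == 1 & !sch$dummy, ]
  expect_equal(nrow(one), 64L)
  expect_equal(sort(one$shot), 0:63)
})

test_that("EPI with Ny = 32, NETL = 4 uses 8 TRs per polarity", {
  p <- sequence_params(TE = 6, TR = 40, FA = 30, FOV = c(64, 64),
                       matrix_size = c(32, 32), VENC = 100, readout = "EPI",
                       NETL = 4L, n_dummy = 0L)
  sch <- sequence_schedule(p)
  one <- sch[sch$venc_axis == "SS" & sch$polarity == 1 & !sch$dummy, ]
  expect_equal(nrow(one), 8L)
  # shot e acquires interleaved lines e + j * n_shots
  tl <- build_timeline(p, "SS", 1, shot = 3L)
  ro <- tl[tl$type == "readout", ]
  expect_equal(ro$ky, c(3L, 11L, 19L, 27L))
  expect_equal(ro$reversed, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("NETL = 1 EPI timeline equals the conventional timeline", {
  base <- list(TE = 5, TR = 30, FA = 25, FOV = c(64, 64),
               matrix_size = c(32, 32), VENC = 120)
  pc <- do.call(sequence_params, c(base, list(readout = "conventional")))
  pe <- do.call(sequence_params, c(base, list(readout = "EPI", NETL = 1L)))
  for (shot in c(0L, 7L, 31L)) {
    tc <- build_timeline(pc, "SS", 1, shot = shot)
    te <- build_timeline(pe, "SS", 1, shot = shot)
    expect_equal(tc, te, tolerance = 1e-12)
  }
})

test_that("first echo is centered at TE and events stay inside TR", {
  p <- sequence_params(TE = 6, TR = 40, FA = 30, FOV = c(64, 64),
                       matrix_size = c(32, 32), VENC = 100, readout = "EPI",
                       NETL = 8L)
  tl <- build_timeline(p, "SS", 1)
  ro <- tl[tl$type == "readout", ]
  expect_equal(ro$t_start[1] + p$t_ACQ / 2, p$TE, tolerance = 1e-12)
  expect_lt(max(tl$t_start + tl$duration), p$TR)
})

test_that("velocity-encode lobes are bipolar and flip with polarity", {
  p <- sequence_params(TE = 5, TR = 30, FA = 25, FOV = c(64, 64),
                       matrix_size = c(32, 32), VENC = 100)
  tp <- build_timeline(p, "SS", +1)
  tm <- build_timeline(p, "SS", -1)
  gp <- tp[tp$type == "grad" & tp$Gz != 0, "Gz"]
  gm <- tm[tm$type == "grad" & tm$Gz != 0, "Gz"]
  expect_equal(gp, c(-1, 1) * p$G_venc)
  expect_equal(gm, -gp)
  # the two lobes have equal duration: zeroth moment vanishes
  durs <- tp[tp$type == "grad" & tp$Gz != 0, "duration"]
  expect_equal(durs[1], durs[2])
})

test_that("configuration errors name the offending constraint", {
  expect_error(sequence_params(TE = 5, TR = 4, FA = 30), "t_ACQ < TE < TR")
  # FOV too small for Nyquist sampling within the gradient limit
  expect_error(sequence_params(TE = 5, TR = 30, FA = 30, t_ACQ = 1,
                               FOV = c(2, 2), matrix_size = c(64, 64),
                               VENC = 100),
               "Nyquist")
  expect_error(sequence_params(TE = 1.2, TR = 30, FA = 30, t_ACQ = 1,
                               FOV = c(64, 64), matrix_size = c(32, 32),
                               VENC = 100),
               "prewinder|overlaps")
  expect_error(sequence_params(TE = 5, TR = 8, FA = 30, FOV = c(64, 64),
                               matrix_size = c(32, 32), VENC = 100,
                               readout = "EPI", NETL = 8L),
               "echo train")
  expect_error(sequence_params(TE = 5, TR = 30, FA = 30,
                               matrix_size = c(32, 32), readout = "EPI",
                               NETL = 5L),
               "divisible")
  expect_error(sequence_params(TE = 5, TR = 30, FA = 30, dimension = "3D",
                               readout = "EPI", NETL = 4L,
                               matrix_size = c(32, 32)),
               "2D only")
})

test_that("3D parameters derive the partition geometry", {
  p <- sequence_params(TE = 3, TR = 40, FA = 15, t_ACQ = 1,
                       FOV = c(25.6, 25.6), matrix_size = c(32, 32),
                       slice_spacing = 2.5, n_partitions = 8L, VENC = 250,
                       dimension = "3D", slab_center = 10)
  expect_equal(p$FOV_z, 20)
  expect_equal(p$venc_axes, c("SS", "PE", "RO"))
  tl <- build_timeline(p, "RO", 1, kz_index = 0L)
  g <- tl[tl$type == "grad", ]
  expect_equal(nrow(g), 3L)           # two venc lobes + combined prewinder
})
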