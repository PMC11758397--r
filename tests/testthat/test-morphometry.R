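stub_morphology <- function() {
  neuron_morphology(data.frame(
    id = 1:6, type = c(1, 3, 3, 4, 2, 2),
    x = c(0, 10, 25, 0, 0, -30), y = c(1000, 1000, 1000, 950, 1060, 1060),
    z = 0, radius = c(8, 1, 1, 1.5, 0.5, 0.5),
    parent = c(-1, 1, 2, 1, 1, 5)))
}

test_that("SWC validation rejects malformed trees and round-trips good ones", {
  m <- stub_morphology()
  p <- tempfile(fileext = ".swc")
  write_swc(m, p)
  expect_equal(as.data.frame(read_swc(p)), as.data.frame(m))
  unlink(p)
  # parent after child
  bad <- data.frame(id = 1:3, type = c(1, 3, 3), x = 0, y = 0, z = 0,
                    radius = 1, parent = c(-1, 3, 1))
  expect_error(neuron_morphology(bad), "parent appears after child")
  expect_error(neuron_morphology(transform(bad, parent = c(-1, 9, 1))),
               "orphan")
  expect_error(neuron_morphology(transform(bad, parent = c(-1, 1, 1),
                                           type = c(1, 7, 3))),
               "unknown SWC type")
  writeLines("1 1 0 0 0 5", p <- tempfile())
  expect_error(read_swc(p), "7 columns")
})

test_that("shrinkage correction scales the quoted factors exactly", {
  m <- neuron_morphology(data.frame(id = 1:2, type = c(1, 3),
                                    x = c(0, 100), y = c(0, 200),
                                    z = c(0, 50), radius = 1,
                                    parent = c(-1, 1)))
  cc <- shrinkage_correct(m)
  expect_equal(c(cc$x[2], cc$y[2], cc$z[2]), c(110, 220, 105))
  expect_equal(cc$radius, m$radius)
  # identity at unit factors; inverse composes to identity
  expect_equal(as.data.frame(shrinkage_correct(m, 1, 1)), as.data.frame(m))
  back <- shrinkage_correct(shrinkage_correct(m), 1 / 1.1, 1 / 2.1)
  expect_equal(as.data.frame(back), as.data.frame(m), tolerance = 1e-12)
  # a purely in-plane segment scales by exactly 1.1
  seg0 <- segment_lengths(m)$length_um
  seg1 <- segment_lengths(shrinkage_correct(m, 1.1, 1))
  inplane <- neuron_morphology(data.frame(id = 1:2, type = c(1, 3),
                                          x = c(0, 30), y = c(0, 40), z = 0,
                                          radius = 1, parent = c(-1, 1)))
  expect_equal(segment_lengths(shrinkage_correct(inplane))$length_um,
               1.1 * segment_lengths(inplane)$length_um)
})

test_that("thickness normalisation scales depth and preserves relative depth", {
  ctx <- layer_context(wm_depth_um = 1800,
                       layer_boundaries_um = c(L4 = 900, L5 = 1250,
                                               L6a = 1620, L6b = 1800))
  m <- neuron_morphology(data.frame(id = 1:2, type = c(1, 2),
                                    x = c(5, 5), y = c(1700, 1750), z = 0,
                                    radius = c(7, 0.5), parent = c(-1, 1)))
  out <- normalize_thickness(m, ctx, 1900)
  expect_equal(out$morphology$y[1], 1700 * 1900 / 1800)
  expect_equal(out$ctx$wm_depth_um, 1900)
  r0 <- morphometrics(m, ctx)$relative_depth
  r1 <- morphometrics(out$morphology, out$ctx)$relative_depth
  expect_equal(r0, r1, tolerance = 1e-12)
  # identity when the target equals the current thickness
  same <- normalize_thickness(m, ctx, 1800)
  expect_equal(same$morphology$y, m$y)
  expect_error(normalize_thickness(m, ctx, -5), "target")
})

test_that("morphometrics follow their definitions on a hand-built tree", {
  ctx <- layer_context()
  # two collinear basal segments of 10 + 20 um; dendrite span 300 um
  m <- neuron_morphology(data.frame(
    id = 1:5, type = c(1, 3, 3, 3, 3),
    x = c(0, 10, 30, -150, 150), y = c(1000, 1000, 1000, 990, 990),
    z = 0, radius = c(8, 1, 1, 1, 1), parent = c(-1, 1, 2, 1, 1)))
  mm <- morphometrics(m, ctx)
  seg3 <- sum(segment_lengths(m)$length_um[segment_lengths(m)$type == 3])
  expect_equal(mm$basal_total_length_um, seg3)
  expect_equal(mm$dendritic_field_span_um, 300)
  expect_equal(mm$soma_depth_um, 1000)
  expect_equal(mm$relative_depth, 1000 / ctx$wm_depth_um)
  expect_equal(mm$soma_perimeter_um, 2 * pi * 8)
  expect_equal(mm$soma_area_um2, pi * 64)
  expect_identical(mm$n_basal_dendrites, 3L)
  expect_true("no_apical_dendrite" %in% attr(mm, "flags"))
  expect_true(is.na(mm$apical_total_length_um))
})

test_that("synthetic archetype totals match ground truth to 1e-9 relative", {
  ctx <- layer_context()
  for (arc in c("upright_pc", "inverted_pc", "multipolar")) {
    gen <- generate_morphology(arc, ctx, seed = 17)
    mm <- morphometrics(gen$morphology, ctx)
    gt <- gen$ground_truth$total_length_um
    expect_equal(mm$axonal_total_length_um, gt[["axon"]],
                 tolerance = 1e-9)
    expect_equal(mm$dendritic_total_length_um, gt[["dendritic"]],
                 tolerance = 1e-9)
  }
})

test_that("totals are invariant to rotation about the depth axis and to
           continuation-node insertion", {
  ctx <- layer_context()
  gen <- generate_morphology("multipolar", ctx, seed = 23)
  m <- gen$morphology
  th <- 0.83
  soma <- m[m$type == 1, ][1, ]
  rx <- soma$x + cos(th) * (m$x - soma$x) - sin(th) * (m$z - soma$z)
  rz <- soma$z + sin(th) * (m$x - soma$x) + cos(th) * (m$z - soma$z)
  rot <- m; rot$x <- rx; rot$z <- rz
  rot <- neuron_morphology(as.data.frame(rot))
  expect_equal(morphometrics(rot, ctx)$dendritic_total_length_um,
               morphometrics(m, ctx)$dendritic_total_length_um,
               tolerance = 1e-9)
  # split one basal segment by a degree-2 node: counts unchanged
  mm0 <- morphometrics(m, ctx)
  seg <- which(m$type == 3 & m$parent != -1)[1]
  par_row <- match(m$parent[seg], m$id)
  mid <- data.frame(id = max(m$id) + 1, type = 3,
                    x = (m$x[seg] + m$x[par_row]) / 2,
                    y = (m$y[seg] + m$y[par_row]) / 2,
                    z = (m$z[seg] + m$z[par_row]) / 2,
                    radius = 1, parent = m$parent[seg])
  m2 <- as.data.frame(m)
  m2$parent[seg] <- mid$id
  m2 <- rbind(m2[seq_len(seg - 1), ], mid, m2[seg:nrow(m2), ])
  m2 <- neuron_morphology(m2)
  mm2 <- morphometrics(m2, ctx)
  expect_identical(mm2$n_basal_branches, mm0$n_basal_branches)
  expect_equal(mm2$basal_total_length_um, mm0$basal_total_length_um,
               tolerance = 1e-9)
})
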