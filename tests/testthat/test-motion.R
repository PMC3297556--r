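# motion: cleft axis, rocking series, direction decomposition, docking angle

ca_structure <- function(coords, chain = "C") {
  n <- nrow(coords)
  at <- data.frame(serial = 1:n, name = "CA", element = "C", res_name = "GLY",
                   res_seq = 1:n, chain_id = chain, icode = "", occupancy = 1,
                   b_factor = 0)
  trajectory(topology(at), coords)
}

test_that("cleft axis of a straight peptide is the chain direction", {
  x <- cbind(3.8 * (1:13), 0, 0)
  st <- ca_structure(x)
  expect_equal(cleft_axis(st, selection(name = "CA")), c(1, 0, 0),
               tolerance = 1e-9)
  # reversing the residue numbering flips the orientation convention
  st_rev <- ca_structure(x[13:1, ])
  expect_equal(cleft_axis(st_rev, selection(name = "CA")), c(-1, 0, 0),
               tolerance = 1e-9)
  expect_error(cleft_axis(ca_structure(x[1:2, ]), selection(name = "CA")),
               "at least 3")
})

test_that("a bulged arc matches the covariance eigenvector oracle", {
  t <- seq(0, pi, length.out = 13)
  x <- cbind(10 * t, 0, 3 * sin(t))       # arc in the xz-plane
  st <- ca_structure(x)
  ax <- cleft_axis(st, selection(name = "CA"))
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc))$vectors[, 1]
  if (sum(ev * (x[13, ] - x[1, ])) < 0) ev <- -ev
  expect_equal(abs(sum(ax * ev)), 1, tolerance = 1e-9)
})

test_that("a trajectory identical to the reference has zero motion", {
  tr <- gen_rocking_complex(amplitude_deg = 0, n_frames = 5)
  ms <- tcr_motion_series(tr, selection(chain = "A", name = "CA"),
                          selection(chain = "T", name = "CA"))
  expect_lt(max(ms$angle_deg), 1e-6)
  expect_lt(max(abs(as.matrix(ms[, c("disp_x", "disp_y", "disp_z")]))), 1e-6)
})

test_that("rocking amplitude and axis are recovered from the generator", {
  tr <- gen_rocking_complex(amplitude_deg = 12, axis = c(0, 0, 1),
                            period = 100, n_frames = 100)
  ms <- tcr_motion_series(tr, selection(chain = "A", name = "CA"),
                          selection(chain = "T", name = "CA"))
  expect_equal(max(ms$angle_deg), 12, tolerance = 0.01)
  expect_equal(ms$angle_deg[26], 12, tolerance = 0.01)  # sin peak
  i <- which.max(ms$angle_deg)
  ax <- unlist(ms[i, c("axis_x", "axis_y", "axis_z")], use.names = FALSE)
  misalign <- acos(min(1, abs(sum(ax * c(0, 0, 1))))) * 180 / pi
  expect_lt(misalign, 1)
})

test_that("amplitude recovery holds across random axes and amplitudes", {
  withr::local_seed(41)
  for (k in 1:5) {
    amp <- runif(1, 2, 30)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    tr <- gen_rocking_complex(amplitude_deg = amp, axis = ax, period = 20,
                              n_frames = 20)
    ms <- tcr_motion_series(tr, selection(chain = "A", name = "CA"),
                            selection(chain = "T", name = "CA"))
    expect_equal(max(ms$angle_deg), amp, tolerance = 0.01)
    i <- which.max(ms$angle_deg)
    got <- unlist(ms[i, c("axis_x", "axis_y", "axis_z")], use.names = FALSE)
    expect_lt(acos(min(1, abs(sum(got * ax)))) * 180 / pi, 1)
  }
})

test_that("rigid motion of the WHOLE complex leaves the series at zero", {
  withr::local_seed(42)
  tr <- gen_rocking_complex(amplitude_deg = 0, n_frames = 4)
  ref <- frame_coords(tr, 1)
  for (f in 2:4)
    tr$coords[f, , ] <- rigid_move(ref, random_rotation(), rnorm(3, sd = 10))
  ms <- tcr_motion_series(tr, selection(chain = "A", name = "CA"),
                          selection(chain = "T", name = "CA"),
                          reference = ref)
  expect_lt(max(ms$angle_deg), 1e-5)
})

test_that("displacement decomposition labels parallel/orthogonal/mixed/static", {
  cleft <- c(1, 0, 0)
  mk <- function(d) {
    s <- data.frame(frame = seq_len(nrow(d)), angle_deg = 1,
                    axis_x = 0, axis_y = 0, axis_z = 1,
                    disp_x = d[, 1], disp_y = d[, 2], disp_z = d[, 3])
    class(s) <- c("motion_series", "data.frame")
    s
  }
  along <- mk(cbind(rnorm(20), 0, 0))
  expect_equal(motion_direction(along, cleft)$parallel_fraction, 1)
  expect_equal(motion_direction(along, cleft)$label, "parallel")
  across <- mk(cbind(0, rnorm(20), 0))
  expect_equal(motion_direction(across, cleft)$parallel_fraction, 0)
  expect_equal(motion_direction(across, cleft)$label, "orthogonal")
  still <- mk(matrix(0, 5, 3))
  expect_equal(motion_direction(still, cleft)$label, "static")
  # isotropic in-plane displacements: fraction near the 2D expectation
  withr::local_seed(43)
  th <- runif(4000, 0, 2 * pi)
  iso <- mk(cbind(cos(th), sin(th), 0))
  md <- motion_direction(iso, cleft)
  # E|cos| = E|sin| = 2/pi, so the expected fraction is 1/2
  expect_equal(md$parallel_fraction, 0.5, tolerance = 0.05)
  expect_equal(md$label, "mixed")
})

test_that("plane projection removes out-of-plane displacement", {
  s <- data.frame(frame = 1:2, angle_deg = 0, axis_x = 0, axis_y = 0,
                  axis_z = 1, disp_x = c(1, 2), disp_y = 0, disp_z = c(5, -5))
  class(s) <- c("motion_series", "data.frame")
  md <- motion_direction(s, c(1, 0, 0), plane_normal = c(0, 0, 1))
  expect_equal(md$parallel_fraction, 1)
})

test_that("docking-angle difference is recovered and symmetric", {
  tr <- gen_rocking_complex(amplitude_deg = 0, n_frames = 1)
  a <- trajectory(tr$topology, frame_coords(tr, 1))
  expect_equal(docking_angle_difference(a, a,
                                        selection(chain = "A", name = "CA"),
                                        selection(chain = "T", name = "CA")),
               0, tolerance = 1e-6)
  # rotate the TCR of a copy by 12 degrees about a chosen axis
  withr::local_seed(44)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  b <- a
  it <- select_atoms(a$topology, selection(chain = "T"))
  pivot <- colMeans(frame_coords(a, 1)[it, ])
  moved <- sweep(sweep(frame_coords(a, 1)[it, ], 2, pivot) %*%
                   t(quat_rotation(12, ax)), 2, pivot, `+`)
  b$coords[1, it, ] <- moved
  msel <- selection(chain = "A", name = "CA")
  tsel <- selection(chain = "T", name = "CA")
  ang_ab <- docking_angle_difference(a, b, msel, tsel)
  ang_ba <- docking_angle_difference(b, a, msel, tsel)
  expect_equal(ang_ab, 12, tolerance = 1e-3)
  expect_equal(ang_ab, ang_ba, tolerance = 1e-6)
})

test_that("motion CSV carries the direction summary", {
  tr <- gen_rocking_complex(n_frames = 20, period = 20)
  ms <- tcr_motion_series(tr, selection(chain = "A", name = "CA"),
                          selection(chain = "T", name = "CA"))
  path <- withr::local_tempfile(fileext = ".csv")
  st <- trajectory(tr$topology, frame_coords(tr, 1))
  write_motion_csv(ms, path, cleft_axis(st, selection(chain = "C", name = "CA")))
  lines <- readLines(path)
  expect_match(lines[1], "label=")
  expect_equal(length(lines), 2 + 20)
})
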