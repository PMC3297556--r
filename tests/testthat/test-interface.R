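# interface: donor/acceptor chemistry, per-frame H-bond and contact detection

# one donor (N with H along +x) and one acceptor O placed at a chosen
# distance from N and angle at the hydrogen
hb_probe <- function(dist, angle_deg) {
  at <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                   element = c("N", "H", "O"),
                   res_name = "GLY", res_seq = c(1, 1, 2),
                   chain_id = c("A", "A", "B"), icode = "", occupancy = 1,
                   b_factor = 0)
  # law of cosines for |H-A| given |N-H| = 1, |N-A| = dist, angle at H
  cth <- cos(angle_deg * pi / 180)
  x <- cth + sqrt(cth^2 - (1 - dist^2))
  acc <- c(1, 0, 0) + x * c(cos(pi - angle_deg * pi / 180),
                            sin(pi - angle_deg * pi / 180), 0)
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), acc)
  top <- topology(at, h_attach = c(NA, 1L, NA))
  list(top = top, coords = coords)
}

probe_formed <- function(dist, angle_deg, criteria = hbond_criteria()) {
  p <- hb_probe(dist, angle_deg)
  da <- assign_donors_acceptors(p$top)
  nrow(hbonds_in_frame(p$coords, da$donors, da$acceptors, criteria)) == 1L
}

test_that("both cutoffs bind independently, boundaries inclusive", {
  expect_true(probe_formed(2.9, 165))
  expect_false(probe_formed(3.6, 180))    # distance alone fails
  expect_false(probe_formed(2.9, 149))    # angle alone fails
  expect_true(probe_formed(3.5, 150))     # both exactly at the boundary
  # the probe geometry itself is validated against its construction
  p <- hb_probe(2.9, 165)
  expect_equal(sqrt(sum((p$coords[3, ] - p$coords[1, ])^2)), 2.9)
})

test_that("donor/acceptor assignment follows the residue chemistry table", {
  at <- data.frame(
    serial = 1:6,
    name = c("N", "H", "OE1", "NE2", "N", "CA"),
    element = c("N", "H", "O", "N", "N", "C"),
    res_name = c("GLY", "GLY", "GLN", "GLN", "PRO", "PRO"),
    res_seq = c(1, 1, 2, 2, 3, 3), chain_id = "A", icode = "",
    occupancy = 1, b_factor = 0)
  top <- topology(at, h_attach = c(NA, 1L, NA, NA, NA, NA))
  da <- assign_donors_acceptors(top)
  expect_equal(da$donors$atom, 1L)              # backbone N with H donates
  expect_true(3L %in% da$acceptors)             # Gln side-chain OE1 accepts
  expect_false(5L %in% da$donors$atom)          # proline N never donates
  # potential mode (no hydrogens): table-based donors, PRO N still excluded
  dap <- assign_donors_acceptors(top, potential = TRUE)
  expect_true(all(c(1L, 4L) %in% dap$donors$atom))
  expect_false(5L %in% dap$donors$atom)
})

test_that("scripted schedules are reproduced frame-exactly", {
  on1 <- c(rep(TRUE, 60), rep(FALSE, 40))
  on2 <- rep(c(TRUE, FALSE), 50)
  tr <- gen_hbond_system(list(on1, on2))
  ser <- hbond_series(tr, selection(chain = "D"), selection(chain = "E"))
  expect_length(ser, 2L)
  by_res <- setNames(ser, vapply(ser, function(s) s$donor$res_seq, 1))
  expect_identical(by_res[["1"]]$formed, on1)
  expect_identical(by_res[["2"]]$formed, on2)
  expect_equal(persistence(by_res[["1"]]), 60)
})

test_that("an all-off schedule and inert groups yield no series", {
  tr <- gen_hbond_system(list(rep(FALSE, 20)))
  ser <- hbond_series(tr, selection(chain = "D"), selection(chain = "E"))
  expect_length(ser, 0L)
})

test_that("overlapping groups are rejected", {
  tr <- gen_hbond_system(list(rep(TRUE, 5)))
  expect_error(hbond_series(tr, selection(chain = "D"), selection()),
               "disjoint")
})

test_that("detection matches the exhaustive all-pairs oracle on random systems", {
  withr::local_seed(21)
  for (rep in 1:4) {
    tr <- random_hbond_trajectory(n_res_a = 6, n_res_b = 6, n_frames = 8)
    ser <- hbond_series(tr, selection(chain = "A"), selection(chain = "B"),
                        merge_equivalent = FALSE)
    got <- series_frame_sets(ser, tr)
    want <- brute_hbond_sets(tr, "A", "B")
    expect_identical(got, want)
  }
})

test_that("bond calls are invariant under a rigid transform of each frame", {
  withr::local_seed(22)
  tr <- random_hbond_trajectory(n_res_a = 5, n_res_b = 5, n_frames = 6)
  ser0 <- hbond_series(tr, selection(chain = "A"), selection(chain = "B"))
  moved <- tr
  for (f in seq_len(n_frames(tr)))
    moved$coords[f, , ] <- rigid_move(frame_coords(tr, f), random_rotation(),
                                      rnorm(3, sd = 20))
  ser1 <- hbond_series(moved, selection(chain = "A"), selection(chain = "B"))
  expect_identical(lapply(ser1, `[[`, "formed"), lapply(ser0, `[[`, "formed"))
  expect_identical(vapply(ser1, `[[`, "", "label"),
                   vapply(ser0, `[[`, "", "label"))
})

test_that("tightening the criteria never adds a bond (monotonicity)", {
  withr::local_seed(23)
  tr <- random_hbond_trajectory(n_res_a = 10, n_res_b = 10, n_frames = 6)
  loose <- hbond_series(tr, selection(chain = "A"), selection(chain = "B"),
                        hbond_criteria(3.5, 150))
  tight <- hbond_series(tr, selection(chain = "A"), selection(chain = "B"),
                        hbond_criteria(3.0, 160))
  loose_map <- setNames(lapply(loose, `[[`, "formed"),
                        vapply(loose, `[[`, "", "label"))
  expect_gt(length(loose), 0)   # the fixture must actually form bonds
  expect_true(all(vapply(tight, `[[`, "", "label") %in% names(loose_map)))
  expect_true(all(vapply(tight, function(s)
    all(loose_map[[s$label]][s$formed]), TRUE)))
})

test_that("equivalent-atom pairs merge into one 1/2 series by per-frame OR", {
  # an ASP with both carboxylate oxygens alternately in range of one donor
  at <- data.frame(
    serial = 1:4, name = c("N", "H", "OD1", "OD2"),
    element = c("N", "H", "O", "O"),
    res_name = c("GLY", "GLY", "ASP", "ASP"),
    res_seq = c(1, 1, 2, 2), chain_id = c("A", "A", "B", "B"), icode = "",
    occupancy = 1, b_factor = 0)
  top <- topology(at, h_attach = c(NA, 1L, NA, NA))
  near <- c(2.9, 0, 0); far <- c(9, 0, 0)
  fr1 <- rbind(c(0, 0, 0), c(1, 0, 0), near, far)   # OD1 bound
  fr2 <- rbind(c(0, 0, 0), c(1, 0, 0), far, near)   # OD2 bound
  fr3 <- rbind(c(0, 0, 0), c(1, 0, 0), far, far)    # neither
  coords <- array(0, c(3, 4, 3))
  coords[1, , ] <- fr1; coords[2, , ] <- fr2; coords[3, , ] <- fr3
  tr <- trajectory(top, coords)
  ser <- hbond_series(tr, selection(chain = "A"), selection(chain = "B"))
  expect_length(ser, 1L)
  expect_equal(ser[[1]]$acceptor$name, "OD1/2")
  expect_identical(ser[[1]]$formed, c(TRUE, TRUE, FALSE))
  # unmerged: two distinct series
  ser2 <- hbond_series(tr, selection(chain = "A"), selection(chain = "B"),
                       merge_equivalent = FALSE)
  expect_length(ser2, 2L)
})

test_that("residue contacts respect the heavy-atom cutoff", {
  at <- data.frame(serial = 1:2, name = "CA", element = "C", res_name = "GLY",
                   res_seq = c(1, 2), chain_id = c("A", "B"), icode = "",
                   occupancy = 1, b_factor = 0)
  top <- topology(at)
  near <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  far <- rbind(c(0, 0, 0), c(4.2, 0, 0))
  expect_equal(nrow(contacts_in_frame(near, top, 1L, 2L, 4.0)), 1L)
  expect_equal(nrow(contacts_in_frame(far, top, 1L, 2L, 4.0)), 0L)
})

test_that("contact pairs match an exhaustive pairwise oracle", {
  withr::local_seed(24)
  tr <- random_hbond_trajectory(n_res_a = 6, n_res_b = 6, n_frames = 1)
  top <- tr$topology
  fr <- frame_coords(tr, 1)
  got <- contacts_in_frame(fr, top, select_atoms(top, selection(chain = "A")),
                           select_atoms(top, selection(chain = "B")), 4.0)
  got_keys <- sort(paste(got$res_a, got$res_b))
  want <- character(0)
  uid <- residue_uid(top)
  a <- top$atoms
  ia <- which(a$chain_id == "A" & a$element != "H")
  ib <- which(a$chain_id == "B" & a$element != "H")
  for (i in ia) for (j in ib)
    if (sqrt(sum((fr[i, ] - fr[j, ])^2)) <= 4.0)
      want <- c(want, paste(uid[i], uid[j]))
  expect_identical(got_keys, sort(unique(want)))
})

test_that("salt bridges are basic-nitrogen to carboxylate pairs only", {
  expect_true(salt_bridge_flag(series_stub("ARG", "NH1/2", "ASP", "OD1/2")))
  expect_true(salt_bridge_flag(series_stub("LYS", "NZ", "GLU", "OE2")))
  expect_true(salt_bridge_flag(series_stub("ASP", "OD1", "ARG", "NH1")))  # symmetric
  expect_false(salt_bridge_flag(series_stub("GLY", "N", "GLY", "O")))
  expect_false(salt_bridge_flag(series_stub("ARG", "N", "ASP", "OD1")))   # backbone N
})

test_that("per-bond CSV export carries persistence and salt-bridge columns", {
  tr <- gen_hbond_system(list(c(rep(TRUE, 3), FALSE)))
  ser <- hbond_series(tr, selection(chain = "D"), selection(chain = "E"))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- hbond_table(ser, path)
  expect_equal(df$n_frames_formed, 3L)
  expect_equal(df$persistence_pct, 75)
  expect_false(df$salt_bridge)
  expect_true(file.exists(path))
  expect_match(readLines(path)[1], "d_max=3.5")
})
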