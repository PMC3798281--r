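single_atom <- function(el = "C") {
  structure_model(data.frame(chain = "A", resno = 1, resname = "A",
                             element = el, x = 0, y = 0, z = 0))
}

test_that("an isolated atom recovers the closed-form sphere area exactly", {
  a <- compute_asa(single_atom("C"))
  expect_equal(a$asa, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
  o <- compute_asa(single_atom("O"))
  expect_equal(o$asa, 4 * pi * (1.52 + 1.4)^2, tolerance = 1e-12)
})

test_that("non-occluding atoms contribute independent areas", {
  m <- structure_model(data.frame(chain = "A", resno = c(1, 2), resname = "A",
                                  element = "C", x = c(0, 100), y = 0, z = 0))
  a <- compute_asa(m)
  expect_equal(sum(a$asa), 2 * 4 * pi * 3.1^2, tolerance = 1e-12)
})

test_that("two overlapping spheres match the analytic intersection formula", {
  for (d in c(1.0, 2.0, 3.5, 5.0)) {
    m <- structure_model(data.frame(chain = "A", resno = c(1, 2), resname = "A",
                                    element = c("C", "O"),
                                    x = c(0, d), y = 0, z = 0))
    est <- sum(attr(compute_asa(m, points = 960), "atom_asa"))
    truth <- two_sphere_area(1.7 + 1.4, 1.52 + 1.4, d)
    expect_equal(est, truth, tolerance = 0.01)
  }
})

test_that("the engine agrees with an independent random-point oracle on small clusters", {
  xyz <- withr::with_seed(7, matrix(rnorm(12 * 3, sd = 2.5), ncol = 3))
  m <- structure_model(data.frame(chain = "A", resno = 1:12, resname = "A",
                                  element = "C", x = xyz[, 1], y = xyz[, 2],
                                  z = xyz[, 3]))
  est <- sum(compute_asa(m, points = 960)$asa)
  oracle <- grid_sasa_oracle(xyz, rep(1.7, 12))
  expect_equal(est, oracle, tolerance = 0.01)
})

test_that("the point set converges: doubling points moves residue ASA < 2%", {
  toy <- make_toy_structure()
  a1 <- compute_asa(toy$model, points = 960)
  a2 <- compute_asa(toy$model, points = 1920)
  rel <- abs(a1$asa - a2$asa) / pmax(a2$asa, 1e-9)
  expect_lt(max(rel[a2$asa > 1]), 0.02)
})

test_that("adding occluders never increases an existing atom's ASA", {
  base <- data.frame(chain = "A", resno = 1:3, resname = "A", element = "C",
                     x = c(0, 3, 6), y = 0, z = 0)
  a0 <- attr(compute_asa(structure_model(base)), "atom_asa")
  more <- rbind(base, data.frame(chain = "A", resno = 4, resname = "A",
                                 element = "C", x = 3, y = 2.5, z = 0))
  a1 <- attr(compute_asa(structure_model(more)), "atom_asa")
  expect_true(all(a1[1:3] <= a0 + 1e-9))
})

test_that("unknown elements error without a fallback radius and succeed with one", {
  m <- single_atom("ZZ")
  expect_error(compute_asa(m), "van der Waals")
  a <- compute_asa(m, fallback_radius = 1.7)
  expect_equal(a$asa, 4 * pi * 3.1^2, tolerance = 1e-12)
})

test_that("per-type average ASA pools residues correctly", {
  mk_table <- function(aa, asa) {
    t <- data.frame(chain = "A", resno = seq_along(aa), icode = "", aa = aa,
                    seq_index = seq_along(aa), asa = asa)
    class(t) <- c("asa_table", "data.frame")
    t
  }
  one <- average_asa_by_type(mk_table("V", 55))
  expect_equal(unname(one["V"]), 55)
  two <- average_asa_by_type(mk_table(c("V", "V", "A"), c(10, 30, 7)))
  expect_equal(unname(two["V"]), 20)
  expect_equal(unname(two["A"]), 7)
  expect_true(is.na(two["W"]))
})

test_that("segment metrics satisfy the algebraic identities and limits", {
  toy <- make_toy_structure()
  asa <- compute_asa(toy$model, points = 240)
  # whole-chain segment: nothing else occludes it, so iso = 0, solv_acc = 100
  n <- nrow(toy$model$residues)
  whole <- segment_metrics(toy$model, "A", 1, n, asa = asa, points = 240)
  expect_equal(whole$iso, 0, tolerance = 1e-12)
  expect_equal(whole$solv_acc, 100, tolerance = 1e-12)
  expect_equal(whole$tot_sa, whole$sasa_obs, tolerance = 1e-12)
  # identity iso + solv_acc/100 = 1 on several segments
  for (s in c(1, 5, 11, 20)) {
    seg <- segment_metrics(toy$model, "A", s, s + 5, asa = asa, points = 240)
    expect_equal(seg$iso + seg$solv_acc / 100, 1, tolerance = 1e-12)
    expect_gte(seg$tot_sa, seg$sasa_obs - 1e-9)
    expect_gte(seg$bur_pref, 0)
  }
  expect_error(segment_metrics(toy$model, "A", n, n + 3, asa = asa, points = 240),
               "lacking coordinates")
})

test_that("isolatedness Z-scores separate a buried core from an exposed tail", {
  toy <- make_toy_structure()
  asa <- compute_asa(toy$model, points = 240)
  core <- iso_zscore_riso(toy$model, "A", toy$core[1], toy$core[2],
                          asa = asa, points = 240)
  tl <- iso_zscore_riso(toy$model, "A", toy$tail[1], toy$tail[2],
                        asa = asa, points = 240)
  expect_gt(core$iso, tl$iso)
  expect_gt(core$z, 0)
  expect_lt(tl$z, 0)
  expect_gt(core$r_iso, 1)
  expect_lt(tl$r_iso, 1)
  expect_equal(core$n_windows, nrow(toy$model$residues) - toy$seg_len + 1)
  expect_true(all(core$window_iso >= -1e-9 & core$window_iso <= 1 + 1e-9))
})

test_that("PDB round trip preserves coordinates and SASA", {
  toy <- make_toy_structure(n_helix = 12, n_tail = 8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(toy$model, f)
  back <- read_structure_pdb(f)
  expect_equal(nrow(back$atoms), nrow(toy$model$atoms))
  expect_equal(back$atoms$x, toy$model$atoms$x, tolerance = 1e-3)
  a1 <- compute_asa(toy$model, points = 240)$asa
  a2 <- compute_asa(back, points = 240)$asa
  expect_equal(a1, a2, tolerance = 1e-3)
})

test_that("secondary-structure binning maps codes and flags missing residues", {
  aprs <- apr_intervals(data.frame(seq_id = "s", start = 1, end = 6))
  all_e <- data.frame(seq_id = "s", pos = 1:6, code = "E")
  r <- bin_secondary_structure(all_e, aprs)
  expect_equal(r$strand, 6L)
  expect_equal(unname(r$fraction["strand"]), 1)
  mixed <- data.frame(seq_id = "s", pos = 1:6,
                      code = c("H", "G", "E", "b", "C", "T"))
  rm_ <- bin_secondary_structure(mixed, aprs)
  expect_equal(rm_$helix, 2L)
  expect_equal(rm_$strand, 2L)
  expect_equal(rm_$coil, 2L)
  expect_warning(bin_secondary_structure(mixed[1:4, ], aprs), "lack")
  r0 <- bin_secondary_structure(mixed, aprs[0, ])
  expect_equal(r0$helix + r0$strand + r0$coil, 0L)
})
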