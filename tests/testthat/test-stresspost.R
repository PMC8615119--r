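make_uniform_field <- function(n_axial = 21, n_circ = 16, value = 100) {
  grid <- tidyr::expand_grid(s = seq(0, 1, length.out = n_axial),
                             theta = seq(0, 360 - 360 / n_circ,
                                         by = 360 / n_circ),
                             surface = c("inner", "outer"))
  grid$S_C <- value
  grid$S_L <- value / 2
  stress_field(grid)
}

test_that("quadrant indexing matches the anatomical convention", {
  expect_equal(quadrant_of(c(0, 45, 90, 135, 180, 225, 270, 315)), 1:8)
  expect_equal(quadrant_of(c(22.4, 22.5, 337.4, 337.5, 359.9)),
               c(1L, 2L, 8L, 1L, 1L))
})

test_that("section bands are non-empty, disjoint, and clipped at the boundary", {
  field <- make_uniform_field(n_axial = 101)
  sec <- extract_sections(field)
  expect_setequal(unique(sec$section), c("A", "B", "C"))
  # band membership count follows from the ring construction
  s_grid <- seq(0, 1, length.out = 101)
  rings_b <- sum(abs(s_grid - 0.5) <= 0.025 + 1e-12)
  expect_equal(rings_b, 5)
  expect_equal(nrow(dplyr::filter(sec, section == "B")),
               rings_b * 16 * 2)
  # disjoint bands: no point is tagged twice at these levels
  expect_equal(anyDuplicated(sec[c("s", "theta", "surface", "section")]), 0)
  # boundary levels are clipped, not errors
  sec_edge <- extract_sections(field, s_levels = c(0, 0.5, 1))
  expect_true(all(sec_edge$s >= 0 & sec_edge$s <= 1))
  expect_error(extract_sections(dplyr::filter(field, s < 0.5),
                                s_levels = c(0.05, 0.25, 0.9)),
               "0.9")
})

test_that("a uniform field summarises to 48 identical quadrant means", {
  qs <- make_uniform_field() |> extract_sections() |> quadrant_summary()
  expect_equal(nrow(qs), 48)
  expect_true(all(qs$mean_S_C == 100))
  expect_true(all(qs$mean_S_L == 50))
  expect_true(all(!qs$missing))
})

test_that("quadrant means are invariant to point order and consistent as weighted means", {
  field <- gen_wall_mesh(arm = 500, noise_cv = 0.05, seed = 8)
  sec <- extract_sections(field)
  qs1 <- quadrant_summary(sec)
  shuffled <- sec[sample(nrow(sec)), ]
  class(shuffled) <- class(sec)
  qs2 <- quadrant_summary(shuffled)
  expect_equal(qs1, qs2)
  # sum over quadrants of mean x count reproduces the section total exactly
  totals <- sec |>
    dplyr::group_by(section) |>
    dplyr::summarise(tot = sum(S_L))
  by_q <- qs1 |>
    dplyr::group_by(section) |>
    dplyr::summarise(tot = sum(mean_S_L * n))
  expect_equal(by_q$tot, totals$tot)
})

test_that("bending fields put the longitudinal maximum in quadrant 7", {
  field <- gen_wall_mesh(arm = 500, seed = 1)
  qs <- field |> extract_sections() |> quadrant_summary()
  inner <- dplyr::filter(qs, surface == "inner", section == "B")
  expect_equal(inner$quadrant[which.max(inner$mean_S_L)], 7L)
  expect_equal(inner$quadrant[which.min(inner$mean_S_L)], 3L)
})

test_that("empty sectors are recorded as missing, never as zero", {
  field <- make_uniform_field() |>
    dplyr::filter(!(quadrant_of(theta) == 4)) |>
    stress_field()
  qs <- field |> extract_sections() |> quadrant_summary()
  q4 <- dplyr::filter(qs, quadrant == 4)
  expect_true(all(q4$missing))
  expect_true(all(is.na(q4$mean_S_C)))
  expect_equal(nrow(qs), 48)
})

test_that("transmural differences flag tensile-inner / compressive-outer quadrants", {
  sym <- make_uniform_field() |> extract_sections() |> quadrant_summary()
  d0 <- transmural_delta(sym)
  expect_true(all(d0$delta_S_L == 0))
  expect_false(any(d0$sign_change_S_L))

  bent <- gen_wall_mesh(arm = 2000, seed = 2) |>
    extract_sections() |> quadrant_summary()
  db <- transmural_delta(bent)
  expect_gt(sum(db$sign_change_S_L), 0)
  # adding a constant that preserves signs must not change the flags
  shifted <- bent
  shifted$mean_S_L <- shifted$mean_S_L +
    ifelse(shifted$mean_S_L > 0, 1, -1) * 0.1
  expect_equal(transmural_delta(shifted)$sign_change_S_L, db$sign_change_S_L)

  only_inner <- dplyr::filter(sym, surface == "inner")
  expect_error(transmural_delta(only_inner), "both")
})

test_that("stress fields round-trip through VTK exactly", {
  field <- gen_wall_mesh(n_axial = 10, n_circ = 12, arm = 300,
                         noise_cv = 0.03, seed = 6)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_stress_vtk(field, path)
  back <- read_stress_vtk(path)
  expect_identical(back$S_C, field$S_C)
  expect_identical(back$S_L, field$S_L)
  expect_identical(back$surface, field$surface)
  expect_identical(back$s, field$s)
  expect_identical(back$phase, field$phase)
  expect_identical(back$x, field$x)
})

test_that("field validation catches malformed inputs", {
  good <- make_uniform_field()
  bad <- good; bad$surface[1] <- "lumen"
  expect_error(stress_field(bad), "surface")
  bad2 <- good; bad2$S_L[1] <- NA
  expect_error(stress_field(bad2), "finite")
  bad3 <- good; bad3$s[1] <- 1.2
  expect_error(stress_field(bad3), "arclength|\\[0, 1\\]")
})
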