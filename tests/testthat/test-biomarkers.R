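test_that("step distance is plain Euclidean distance", {
  expect_equal(step_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(step_distance(c(10, 10), c(10, 10)), 0)
  set.seed(7)
  walk <- data.frame(x = cumsum(rnorm(101)), y = cumsum(rnorm(101)))
  acc <- 0
  for (k in 1:100)
    acc <- acc + sqrt((walk$x[k + 1] - walk$x[k])^2 + (walk$y[k + 1] - walk$y[k])^2)
  lg <- make_log(data.frame(x = walk$x + 1280, y = walk$y + 500))
  expect_equal(med_total(lg), acc, tolerance = 1e-12)
})

test_that("METRtotal is Te over the evaluation cap", {
  xy <- straight_path(c(1280, 500), c(1290, 900), 3601)
  ev <- data.frame(cube_id = c("left", "right", "bottom", "top"),
                   sample_index = c(60L, 120L, 180L, 3600L))
  expect_equal(metr_total(make_log(xy, ev)), 0.5)          # Te = 60 of 120

  incomplete <- make_log(xy, ev[1:3, ])
  expect_equal(metr_total(incomplete), 1.0)

  ev2 <- ev; ev2$sample_index[4] <- 1872L                  # Te = 31.2 s
  lg2 <- make_log(straight_path(c(1280, 500), c(1290, 900), 1873), ev2)
  expect_equal(metr_total(lg2), 0.26)
})

test_that("MEDtotal sums per-step distances up to the Te sample", {
  xy <- data.frame(x = 1280 + 3 * (0:10), y = 500 + 4 * (0:10))
  expect_equal(med_total(make_log(xy)), 50)                # 10 steps of 5 px
  still <- make_log(data.frame(x = rep(1280, 50), y = rep(500, 50)))
  expect_equal(med_total(still), 0)
  # drift logged after the final elimination is excluded
  ev <- data.frame(cube_id = c("left", "right", "bottom", "top"),
                   sample_index = c(1L, 2L, 3L, 5L))
  expect_equal(med_total(make_log(xy, ev)), 25)            # 5 steps only
})

test_that("METfirst is the first elimination time and missing without events", {
  xy <- straight_path(c(1280, 500), c(1280, 560), 100)
  ev <- data.frame(cube_id = "left", sample_index = 67L)
  expect_equal(met_first(make_log(xy, ev)), 67 / 60)
  expect_true(is.na(met_first(make_log(xy))))
  sim <- simulate_trial(fast_profile(), seed = 5)
  expect_equal(met_first(sim), sim$events$t_s[1])
})

test_that("MEEfirst scores a straight contact-stopping approach as 1 and a retrace as 2", {
  sc <- default_scene()
  # left cube at (480,500), start (1280,500): contact distance D = 800 - 90
  D <- 710
  straight <- straight_path(c(1280, 500), c(1280 - D, 500), 201)
  ev <- data.frame(cube_id = "left", sample_index = 200L)
  expect_equal(mee_first(make_log(straight, ev, sc)), 1.0, tolerance = 0.02)

  out <- straight_path(c(1280, 500), c(1280 - D / 2, 500), 51)
  back <- straight_path(c(1280 - D / 2, 500), c(1280, 500), 51)[-1, ]
  fwd <- straight_path(c(1280, 500), c(1280 - D, 500), 101)[-1, ]
  retrace <- rbind(out, back, fwd)
  ev2 <- data.frame(cube_id = "left", sample_index = nrow(retrace) - 1L)
  expect_equal(mee_first(make_log(retrace, ev2, sc)), 2.0, tolerance = 0.02)
})

test_that("MEEfirst rejects degenerate start-on-cube geometry", {
  sc <- scene_config(cube_centers = list(top = c(1280, 1250),
                                         bottom = c(1280, 150),
                                         left = c(1340, 500),
                                         right = c(2080, 500)))
  xy <- straight_path(c(1280, 500), c(1340, 500), 10)
  ev <- data.frame(cube_id = "left", sample_index = 9L)
  expect_error(mee_first(make_log(xy, ev, sc)), "degenerate geometry")
})

test_that("crossing detection finds the earliest upward midline crossing only", {
  sc <- default_scene()                                    # obstacle_y = 850
  cr <- detect_crossing(make_log(y_path(c(800, 840, 860)), scene = sc))
  expect_equal(cr$crossing_index, 1)                       # the 840 -> 860 step
  expect_equal(cr$crossing_t_s, 2 / 60)

  expect_null(detect_crossing(make_log(y_path(c(800, 840, 845)), scene = sc)))

  osc <- detect_crossing(make_log(y_path(c(800, 860, 840, 900, 820, 880)),
                                  scene = sc))
  expect_equal(osc$crossing_index, 0)                      # earliest, never reset
  expect_equal(osc$crossing_t_s, 1 / 60)
})

test_that("post-crossing time and distance follow Te - Tcrossing", {
  sc <- default_scene()
  y <- c(rep(800, 1200), rep(900, 1801))                   # first above at i = 1200
  ev <- data.frame(cube_id = c("left", "right", "bottom", "top"),
                   sample_index = c(10L, 20L, 30L, 3000L)) # Te = 50 s
  lg <- make_log(y_path(y), ev, sc)
  cm <- crossing_metrics(lg)
  expect_equal(cm$crossing_t_s, 20)
  expect_equal(cm$et_crossing_s, 30)

  # crossing at the final elimination instant
  y2 <- c(rep(800, 100), 900)
  ev2 <- data.frame(cube_id = c("left", "right", "bottom", "top"),
                    sample_index = c(10L, 20L, 30L, 100L))
  cm2 <- crossing_metrics(make_log(y_path(y2), ev2, sc))
  expect_equal(cm2$et_crossing_s, 0)
  expect_equal(cm2$ed_crossing_px, 0)

  # no crossing: both metrics missing
  cm3 <- crossing_metrics(make_log(y_path(rep(800, 50)), scene = sc))
  expect_true(is.na(cm3$et_crossing_s) && is.na(cm3$ed_crossing_px))
})

test_that("above-obstacle metrics count whole steps spent above the midline", {
  sc <- default_scene()
  ab0 <- above_metrics(make_log(y_path(rep(700, 100)), scene = sc))
  expect_equal(ab0$et_above_s, 0)
  expect_equal(ab0$ed_above_px, 0)

  # 600 consecutive above-midline steps at 60 Hz last exactly 10 s
  y <- c(rep(800, 10), rep(900, 601), rep(800, 10))
  ab <- above_metrics(make_log(y_path(y), scene = sc))
  expect_equal(ab$et_above_s, 10)
})

test_that("the full extractor agrees with per-operation oracles and contracts", {
  lg <- simulate_trial(agent_profile(), seed = 101)
  bm <- extract_biomarkers(lg)
  orc <- oracle_extract(lg)
  for (f in names(orc))
    if (is.numeric(orc[[f]]))
      expect_field_equal(bm[[f]], orc[[f]], tol = 1e-9, label = f)

  # never crosses: crossing-dependent fields missing, above metrics zero
  sc <- default_scene()
  low <- make_log(y_path(rep(500, 200)), scene = sc)
  bm2 <- extract_biomarkers(low)
  expect_true(is.na(bm2$et_crossing_s) && is.na(bm2$ed_crossing_px) &&
              is.na(bm2$crossing_t_s))
  expect_equal(bm2$et_above_s, 0)
  expect_equal(bm2$ed_above_px, 0)
  expect_true(is.na(bm2$met_first_s))                      # no eliminations

  # stationary incomplete trial
  still <- make_log(data.frame(x = rep(1280, 100), y = rep(500, 100)), scene = sc)
  bm3 <- extract_biomarkers(still)
  expect_equal(bm3$metr_total, 1.0)
  expect_equal(bm3$med_total_px, 0)
  expect_false(bm3$complete)
})

test_that("distance biomarkers are translation invariant and scale equivariantly", {
  base_sc <- default_scene()
  lg <- simulate_trial(agent_profile(), base_sc, seed = 55)
  bm <- extract_biomarkers(lg)
  dist_fields <- c("med_total_px", "mee_first", "ed_crossing_px", "ed_above_px")
  time_fields <- c("metr_total", "met_first_s", "et_crossing_s", "et_above_s",
                   "crossing_t_s")

  shift <- c(40, -25)
  shift_scene <- base_sc
  shift_scene$sphere_start <- base_sc$sphere_start + shift
  shift_scene$cube_centers <- lapply(base_sc$cube_centers, `+`, shift)
  shift_scene$obstacle_y_px <- base_sc$obstacle_y_px + shift[2]
  shift_scene$obstacle_x_min_px <- base_sc$obstacle_x_min_px + shift[1]
  shift_scene$obstacle_x_max_px <- base_sc$obstacle_x_max_px + shift[1]
  shifted <- trajectory_log(lg$participant_id, validate_scene(shift_scene),
                            data.frame(x = lg$samples$x + shift[1],
                                       y = lg$samples$y + shift[2]),
                            lg$events[, c("cube_id", "sample_index")])
  bms <- extract_biomarkers(shifted)
  for (f in c(dist_fields, time_fields))
    expect_field_equal(bms[[f]], bm[[f]], tol = 1e-9, label = paste("shift", f))

  s <- 0.5
  scale_scene <- base_sc
  for (f in c("screen_width_px", "screen_height_px", "sphere_radius_px",
              "cube_half_size_px", "obstacle_y_px", "obstacle_x_min_px",
              "obstacle_x_max_px", "obstacle_thickness_px"))
    scale_scene[[f]] <- base_sc[[f]] * s
  scale_scene$sphere_start <- base_sc$sphere_start * s
  scale_scene$cube_centers <- lapply(base_sc$cube_centers, `*`, s)
  scaled <- trajectory_log(lg$participant_id, validate_scene(scale_scene),
                           data.frame(x = lg$samples$x * s, y = lg$samples$y * s),
                           lg$events[, c("cube_id", "sample_index")])
  bmc <- extract_biomarkers(scaled)
  for (f in setdiff(dist_fields, "mee_first"))
    expect_field_equal(bmc[[f]], bm[[f]] * s, tol = 1e-9, label = paste("scale", f))
  expect_field_equal(bmc$mee_first, bm$mee_first, tol = 1e-9, label = "scale mee") # ratio
  for (f in time_fields)
    expect_field_equal(bmc[[f]], bm[[f]], tol = 1e-9, label = paste("scale", f))
})

test_that("time reversal keeps the first-upward-crossing rule consistent", {
  sc <- default_scene()
  pal <- c(800, 820, 860, 880, 860, 820, 800)              # palindrome
  cr <- detect_crossing(make_log(y_path(pal), scene = sc))
  crr <- detect_crossing(make_log(y_path(rev(pal)), scene = sc))
  expect_equal(cr$crossing_index, 1)
  expect_identical(cr, crr)

  asym <- c(800, 900, 860, 920, 700)
  cr2 <- detect_crossing(make_log(y_path(asym), scene = sc))
  cr2r <- detect_crossing(make_log(y_path(rev(asym)), scene = sc))
  expect_equal(cr2$crossing_index, 0)                      # 800 -> 900
  expect_equal(cr2r$crossing_index, 0)                     # 700 -> 920
})

test_that("batch extraction yields one row per trial and survives bad logs", {
  logs <- simulate_trials(3, fast_profile(), seed = 9)
  tab <- extract_cohort(logs)
  expect_equal(nrow(tab), 3)
  expect_true(all(sep_biomarker_names(tab) %in% names(tab)))
  expect_true(all(tab$complete))
})
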