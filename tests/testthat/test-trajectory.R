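test_that("uniform eastward wind gives the closed-form displacement", {
  g <- test_grid(u = 10, v = 0, temp = 20)
  w <- fixed_window(duration_h = 1)
  rel <- release_spec(24, 97.83, "2019-04-26", "forward", w)
  trs <- simulate_trajectories(rel, g, trajectory_params(altitudes_agl = 500))
  tr <- trs[[1]]
  expect_equal(nrow(tr$points), 7) # 1 h / 10 min + 1
  dlon <- tr$endpoint$lon - 97.83
  expect_equal(dlon, 36000 / (111320 * cos(24 * pi / 180)),
               tolerance = 1e-6)
  expect_equal(tr$endpoint$lat, 24) # latitude untouched by pure u
  expect_identical(tr$termination, "window_end")
})

test_that("zero wind keeps every point at the origin until the window ends", {
  g <- test_grid(u = 0, v = 0, temp = 20)
  w <- fixed_window(duration_h = 12)
  rel <- release_spec(24, 97.83, "2019-04-26", "forward", w)
  tr <- simulate_trajectories(rel, g, trajectory_params(altitudes_agl = 300))[[1]]
  expect_equal(nrow(tr$points), 73) # 1 + 12 h / 10 min
  expect_true(all(tr$points$lat == 24))
  expect_true(all(tr$points$lon == 97.83))
  expect_identical(tr$termination, "window_end")
})

test_that("temperature below threshold stops flight at take-off on all layers", {
  g <- test_grid(u = 10, v = 5, temp = 10)
  w <- fixed_window()
  rel <- release_spec(24, 97.83, "2019-04-26", "forward", w)
  trs <- simulate_trajectories(rel, g, trajectory_params())
  expect_length(trs, 10)
  for (tr in trs) {
    expect_identical(tr$termination, "temperature_stop")
    expect_equal(nrow(tr$points), 1)
    expect_equal(tr$endpoint$lat, 24)
  }
})

test_that("the 13.1 C gate is a strict threshold", {
  w <- fixed_window(duration_h = 2)
  rel <- release_spec(24, 97.83, "2019-04-26", "forward", w)
  p <- trajectory_params(altitudes_agl = 500)
  cold <- simulate_trajectories(rel, test_grid(temp = 13.0), p)[[1]]
  warm <- simulate_trajectories(rel, test_grid(temp = 13.2), p)[[1]]
  expect_identical(cold$termination, "temperature_stop")
  expect_identical(warm$termination, "window_end")
  expect_gt(nrow(warm$points), 1)
  # threshold set to -Inf / +Inf bracket the gate completely
  never <- simulate_trajectories(rel, test_grid(temp = -40),
                                 trajectory_params(altitudes_agl = 500,
                                                   temp_threshold = -Inf))[[1]]
  expect_false(identical(never$termination, "temperature_stop"))
  always <- simulate_trajectories(rel, test_grid(temp = 30),
                                  trajectory_params(altitudes_agl = 500,
                                                    temp_threshold = Inf))[[1]]
  expect_identical(always$termination, "temperature_stop")
})

test_that("continuous gate mode stops mid-flight when air turns cold", {
  # temperature falls with height; pick a grid whose east side is cold by
  # making temperature depend on longitude through a hand-edited array
  g <- test_grid(u = 20, v = 0, temp = 20, lon = c(88, 100))
  cold_lon <- g$lons >= 99
  g$temperature[, , , cold_lon] <- 5
  w <- fixed_window(duration_h = 12)
  rel <- release_spec(24, 97.8, "2019-04-26", "forward", w)
  tr <- simulate_trajectories(
    rel, g, trajectory_params(altitudes_agl = 500,
                              temp_gate = "continuous"))[[1]]
  expect_identical(tr$termination, "temperature_stop")
  expect_gt(nrow(tr$points), 1)
  # take-off-only mode flies through the same cold air
  tr2 <- simulate_trajectories(
    rel, g, trajectory_params(altitudes_agl = 500))[[1]]
  expect_false(identical(tr2$termination, "temperature_stop"))
})

test_that("per-step displacement equals wind x step against a step oracle", {
  set.seed(31)
  g <- test_grid(u = 0, v = 0, temp = 20)
  dims <- dim(g$u)
  g$u <- array(rnorm(prod(dims), 5, 3), dims)
  g$v <- array(rnorm(prod(dims), 2, 3), dims)
  w <- fixed_window(duration_h = 3)
  rel <- release_spec(24, 96, "2019-04-26", "forward", w)
  tr <- simulate_trajectories(rel, g, trajectory_params(altitudes_agl = 400))[[1]]
  p <- tr$points
  for (i in seq_len(nrow(p) - 1)) {
    dlat_want <- p$v[i] * 600 / 110574
    dlon_want <- p$u[i] * 600 / (111320 * cos(p$lat[i] * pi / 180))
    expect_equal(p$lat[i + 1] - p$lat[i], dlat_want, tolerance = 1e-9)
    expect_equal(p$lon[i + 1] - p$lon[i], dlon_want, tolerance = 1e-9)
  }
  # recorded u/v/T match an independent re-sample of the field
  for (i in seq_len(nrow(p))) {
    s <- oracle_sample(g, p$time[i], p$lat[i], p$lon[i], 400)
    expect_equal(p$u[i], s$u, tolerance = 1e-9)
    expect_equal(p$v[i], s$v, tolerance = 1e-9)
  }
})

test_that("steady uniform displacement is linear in duration and altitude-free", {
  # pure zonal wind so the metres-per-degree factor stays fixed
  g <- test_grid(u = 8, v = 0, temp = 20)
  rel1 <- release_spec(24, 95, "2019-04-26", "forward",
                       fixed_window(duration_h = 2))
  rel2 <- release_spec(24, 95, "2019-04-26", "forward",
                       fixed_window(duration_h = 4))
  p <- trajectory_params(altitudes_agl = c(100, 600, 1000))
  t1 <- simulate_trajectories(rel1, g, p)
  t2 <- simulate_trajectories(rel2, g, p)
  d1 <- t1[[1]]$endpoint$lon - 95
  d2 <- t2[[1]]$endpoint$lon - 95
  expect_equal(d2 / d1, 2, tolerance = 1e-9)
  # meridional displacement is linear too (dlat has a fixed conversion)
  gv <- test_grid(u = 0, v = 4, temp = 20)
  l1 <- simulate_trajectories(rel1, gv, p)[[1]]$endpoint$lat - 24
  l2 <- simulate_trajectories(rel2, gv, p)[[1]]$endpoint$lat - 24
  expect_equal(l2 / l1, 2, tolerance = 1e-9)
  # altitude independence in a height-uniform field
  lons <- vapply(t1, function(tr) tr$endpoint$lon, numeric(1))
  expect_equal(max(lons) - min(lons), 0, tolerance = 1e-12)
})

test_that("backward runs retrace forward runs in a steady field", {
  g <- test_grid(u = 7, v = 3, temp = 20)
  w <- fixed_window(duration_h = 10)
  fwd <- simulate_trajectories(
    release_spec(23.5, 95, "2019-04-26", "forward", w), g,
    trajectory_params(altitudes_agl = 500))[[1]]
  ep <- fwd$endpoint
  bwd <- simulate_trajectories(
    release_spec(ep$lat, ep$lon, "2019-04-26", "backward", w), g,
    trajectory_params(altitudes_agl = 500))[[1]]
  expect_equal(bwd$endpoint$lat, 23.5, tolerance = 1e-6)
  expect_equal(bwd$endpoint$lon, 95, tolerance = 1e-4)
  # and times decrease along the backward trajectory
  expect_true(all(diff(as.numeric(bwd$points$time)) < 0))
})

test_that("boundary exit keeps the last inside point and no point leaves the domain", {
  g <- test_grid(u = 30, v = 0, temp = 20, lon = c(95, 99))
  w <- fixed_window(duration_h = 12)
  tr <- simulate_trajectories(
    release_spec(24, 98, "2019-04-26", "forward", w), g,
    trajectory_params(altitudes_agl = 500))[[1]]
  expect_identical(tr$termination, "boundary_exit")
  expect_true(all(tr$points$lon <= 99))
  expect_true(all(tr$points$lon >= 95))
  # the very next Euler step from the endpoint would leave the domain
  ep <- tr$endpoint
  nxt_lon <- ep$lon + ep$u * 600 / (111320 * cos(ep$lat * pi / 180))
  expect_gt(nxt_lon, 99)
})

test_that("endpoints are the latest points and accumulate the per-step drift", {
  g <- test_grid(u = 10, v = -5, temp = 20)
  w <- fixed_window(duration_h = 6)
  trs <- simulate_trajectories(
    release_spec(25, 95, "2019-04-26", "forward", w), g,
    trajectory_params(altitudes_agl = c(200, 800)))
  eps <- trajectory_endpoints(trs)
  expect_equal(nrow(eps), 2)
  for (i in 1:2) {
    p <- trs[[i]]$points
    expect_equal(eps$lat[i], p$lat[nrow(p)])
    expect_equal(eps$lon[i], p$lon[nrow(p)])
    # closed-form accumulation over the recorded steps
    lat_acc <- 25 + sum(p$v[-nrow(p)]) * 600 / 110574
    expect_equal(eps$lat[i], lat_acc, tolerance = 1e-9)
  }
  expect_identical(unique(eps$season), "spring")
  # a temperature-stopped run's endpoint is its origin
  cold <- simulate_trajectories(
    release_spec(25, 95, "2019-04-26", "forward", w),
    test_grid(temp = 5), trajectory_params(altitudes_agl = 200))
  ec <- trajectory_endpoints(cold)
  expect_equal(ec$lat, 25)
  expect_equal(ec$lon, 95)
})

test_that("midpoint integrator agrees with euler in a uniform field", {
  g <- test_grid(u = 6, v = 2, temp = 20)
  w <- fixed_window(duration_h = 4)
  rel <- release_spec(24, 95, "2019-04-26", "forward", w)
  e <- simulate_trajectories(rel, g, trajectory_params(
    altitudes_agl = 500, integrator = "euler"))[[1]]
  m <- simulate_trajectories(rel, g, trajectory_params(
    altitudes_agl = 500, integrator = "midpoint"))[[1]]
  expect_equal(m$endpoint$lon, e$endpoint$lon, tolerance = 1e-6)
  expect_equal(m$endpoint$lat, e$endpoint$lat, tolerance = 1e-9)
})

test_that("batch enumeration is complete, ordered and deterministic", {
  g <- make_uniform_field(
    5, 2, 20, domain(c(18, 30), c(88, 106), c(0, 2000),
                     c("2019-04-25 00:00", "2019-11-05 00:00")),
    resolution = list(n_time = 30, n_height = 4, n_lat = 5, n_lon = 5))
  s <- ruili_site()
  b <- batch_simulate(s, c("2019-04-26", "2019-11-02"),
                      c("forward", "backward"), g,
                      trajectory_params(altitudes_agl = seq(100, 1000, 100)))
  expect_equal(nrow(b$failures), 0)
  expect_length(b$trajectories, 4) # 2 dates x 2 directions
  eps <- trajectory_endpoints(b$trajectories)
  expect_equal(nrow(eps), 40) # x 10 altitudes
  b2 <- batch_simulate(s, c("2019-04-26", "2019-11-02"),
                       c("forward", "backward"), g,
                       trajectory_params(altitudes_agl = seq(100, 1000, 100)))
  expect_equal(trajectory_endpoints(b2$trajectories), eps)
  # a single-date batch equals the direct call
  w <- flight_window(s, "2019-04-26")
  direct <- simulate_trajectories(
    release_spec(s$lat, s$lon, "2019-04-26", "forward", w), g,
    trajectory_params(altitudes_agl = seq(100, 1000, 100)))
  one <- batch_simulate(s, "2019-04-26", "forward", g,
                        trajectory_params(altitudes_agl = seq(100, 1000, 100)))
  expect_equal(trajectory_endpoints(one$trajectories),
               trajectory_endpoints(direct))
})

test_that("batch reports per-run failures without aborting", {
  # grid whose time range misses the autumn night entirely
  g <- test_grid(time = c("2019-04-25 00:00", "2019-04-28 00:00"))
  s <- ruili_site()
  b <- batch_simulate(s, c("2019-04-26", "2019-11-02"), "forward", g,
                      trajectory_params(altitudes_agl = 500))
  expect_length(b$trajectories, 1)
  expect_equal(nrow(b$failures), 1)
  expect_match(b$failures$message, "time range|domain")
})

test_that("out-of-domain releases and windows error cleanly", {
  g <- test_grid()
  w <- fixed_window()
  expect_error(simulate_trajectories(
    release_spec(50, 98, "2019-04-26", "forward", w), g,
    trajectory_params(altitudes_agl = 500)), "outside")
  w_off <- fixed_window(start_utc = "2019-06-01 12:00:00")
  expect_error(simulate_trajectories(
    release_spec(24, 98, "2019-06-01", "forward", w_off), g,
    trajectory_params(altitudes_agl = 500)), "time range")
})

test_that("trajectory CSV and endpoint GeoJSON exports round-trip the data", {
  g <- test_grid(u = 5, v = 5, temp = 20)
  w <- fixed_window(duration_h = 2)
  trs <- simulate_trajectories(
    release_spec(24, 96, "2019-04-26", "forward", w), g,
    trajectory_params(altitudes_agl = c(100, 200)))
  csv <- tempfile(fileext = ".csv")
  gj <- tempfile(fileext = ".geojson")
  on.exit(unlink(c(csv, gj)))
  write_trajectories_csv(trs, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), sum(vapply(trs, function(t) nrow(t$points),
                                      integer(1))))
  eps <- trajectory_endpoints(trs)
  write_endpoints_geojson(eps, gj)
  parsed <- jsonlite::fromJSON(gj, simplifyVector = FALSE)
  expect_equal(length(parsed$features), 2)
  expect_equal(parsed$features[[1]]$geometry$coordinates[[1]],
               eps$lon[1])
})
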