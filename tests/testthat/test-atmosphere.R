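test_that("uniform fields carry the constants everywhere and sample to them", {
  g <- make_uniform_field(10, 0, 20, domain(c(18, 30), c(88, 104)))
  expect_true(all(g$u == 10))
  expect_true(all(g$v == 0))
  expect_true(all(g$temperature == 20))
  # sampling anywhere inside returns the constants (interpolation of a
  # constant is the constant)
  set.seed(11)
  for (i in 1:20) {
    s <- sample_field(g,
                      g$times[1] + runif(1, 0, diff(range(as.numeric(g$times)))),
                      runif(1, 18, 30), runif(1, 88, 104), runif(1, 0, 2000))
    expect_equal(s$u, 10)
    expect_equal(s$v, 0)
    expect_equal(s$temperature, 20)
  }
  g0 <- make_uniform_field(0, 0, 20, domain(c(18, 30), c(88, 104)))
  expect_true(all(g0$u == 0) && all(g0$v == 0))
})

test_that("degenerate domains and bad resolutions are rejected", {
  expect_error(domain(c(30, 18), c(88, 104)), "degenerate")
  expect_error(domain(c(18, 30), c(88, 104), height = c(0, 9000)),
               "5000")
  expect_error(make_uniform_field(1, 1, 20, domain(c(18, 30), c(88, 104)),
                                  resolution = list(n_time = 1, n_height = 2,
                                                    n_lat = 2, n_lon = 2)),
               ">= 2 nodes")
})

test_that("monsoon fields have season-consistent wind signs and a linear lapse", {
  d <- domain(c(18, 30), c(88, 104))
  for (seed in c(NULL, 3, 17)) {
    sp <- make_monsoon_field("spring", 5, 25, 0.65, d, seed = seed)
    expect_true(all(sp$u > 0) && all(sp$v > 0))
    au <- make_monsoon_field("autumn", 5, 25, 0.65, d, seed = seed)
    expect_true(all(au$u < 0) && all(au$v < 0))
  }
  sp <- make_monsoon_field("spring", 5, 25, 0.65, d,
                           resolution = list(n_time = 3, n_height = 11,
                                             n_lat = 3, n_lon = 3))
  # temperature at 1000 m AGL is 6.5 C cooler than at the surface
  i1000 <- which(sp$heights_agl == 1000)
  i0 <- which(sp$heights_agl == 0)
  expect_equal(sp$temperature[1, i1000, 1, 1],
               sp$temperature[1, i0, 1, 1] - 6.5)
  expect_error(make_monsoon_field("summer", 5, 25), "arg")
})

test_that("quadrilinear sampling is exact at nodes and linear midway", {
  set.seed(42)
  d <- domain(c(18, 30), c(88, 104))
  ax <- list(n_time = 4, n_height = 4, n_lat = 5, n_lon = 5)
  g <- make_uniform_field(0, 0, 0, d, ax)
  dims <- dim(g$u)
  g$u <- array(rnorm(prod(dims)), dims)
  g$v <- array(rnorm(prod(dims)), dims)
  g$temperature <- array(rnorm(prod(dims), 20, 5), dims)
  # nodal identity
  for (i in 1:5) {
    it <- sample(dims[1], 1); ih <- sample(dims[2], 1)
    ila <- sample(dims[3], 1); ilo <- sample(dims[4], 1)
    s <- sample_field(g, g$times[it], g$lats[ila], g$lons[ilo],
                      g$heights_agl[ih])
    expect_equal(s$u, g$u[it, ih, ila, ilo])
    expect_equal(s$temperature, g$temperature[it, ih, ila, ilo])
  }
  # linear midpoint along one axis
  g2 <- g
  g2$u[] <- 10
  g2$u[, , , 2] <- 20
  g2$u[, , , 1] <- 10
  mid_lon <- (g$lons[1] + g$lons[2]) / 2
  s <- sample_field(g2, g$times[1], g$lats[1], mid_lon, g$heights_agl[1])
  expect_equal(s$u, 15)
})

test_that("random queries match the 16-corner weighted-sum oracle to 1e-9", {
  set.seed(99)
  d <- domain(c(18, 30), c(88, 104))
  g <- make_uniform_field(0, 0, 0, d, list(n_time = 4, n_height = 4,
                                           n_lat = 5, n_lon = 5))
  dims <- dim(g$u)
  g$u <- array(rnorm(prod(dims)), dims)
  g$v <- array(rnorm(prod(dims)), dims)
  g$temperature <- array(rnorm(prod(dims), 15, 8), dims)
  tr <- range(as.numeric(g$times))
  for (i in 1:50) {
    t <- tr[1] + runif(1) * diff(tr)
    lat <- runif(1, 18, 30); lon <- runif(1, 88, 104)
    h <- runif(1, 0, 2000)
    got <- sample_field(g, as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
                        lat, lon, h)
    want <- oracle_sample(g, t, lat, lon, h)
    expect_equal(got$u, want$u, tolerance = 1e-9)
    expect_equal(got$v, want$v, tolerance = 1e-9)
    expect_equal(got$temperature, want$temperature, tolerance = 1e-9)
    # convex combination: bounded by the enclosing corner extremes
    expect_gte(got$u, min(g$u) - 1e-12)
    expect_lte(got$u, max(g$u) + 1e-12)
  }
  expect_error(sample_field(g, g$times[1], 50, 96, 500), "outside")
})

test_that("NetCDF round trip preserves coordinates and fields", {
  g <- make_monsoon_field("spring", 5, 25, seed = 5,
                          domain = domain(c(20, 28), c(92, 102)))
  g$grid_spacing_km <- 10
  path <- tempfile(fileext = ".nc")
  on.exit(unlink(path))
  write_wind_netcdf(g, path)
  g2 <- read_wind_netcdf(path)
  expect_equal(as.numeric(g2$times), as.numeric(g$times))
  expect_equal(g2$heights_agl, g$heights_agl)
  expect_equal(g2$lats, g$lats)
  expect_equal(g2$lons, g$lons)
  expect_equal(g2$u, g$u, tolerance = 1e-12)
  expect_equal(g2$v, g$v, tolerance = 1e-12)
  expect_equal(g2$temperature, g$temperature, tolerance = 1e-12)
  expect_equal(g2$grid_spacing_km, 10)
})

test_that("NetCDF reader names missing variables, converts Kelvin and flips descending axes", {
  g <- test_grid()
  path <- tempfile(fileext = ".nc")
  on.exit(unlink(path), add = TRUE)
  write_wind_netcdf(g, path)
  expect_error(read_wind_netcdf(path, var_names = c(u = "u", v = "vv",
                                                    temperature = "T")),
               "vv")
  expect_error(read_wind_netcdf(tempfile(fileext = ".nc")), "no such file")

  # hand-build a file with descending latitudes and Kelvin temperature
  path2 <- tempfile(fileext = ".nc")
  on.exit(unlink(path2), add = TRUE)
  lats_desc <- c(30, 25, 20)
  dim_time <- ncdf4::ncdim_def("time", "hours since 2019-04-26 00:00:00", 0:2)
  dim_h <- ncdf4::ncdim_def("height", "m", c(0, 1000))
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lats_desc)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", c(90, 95, 100))
  dims <- list(dim_lon, dim_lat, dim_h, dim_time)
  vu <- ncdf4::ncvar_def("u", "m s-1", dims, prec = "double")
  vv <- ncdf4::ncvar_def("v", "m s-1", dims, prec = "double")
  vt <- ncdf4::ncvar_def("T", "K", dims, prec = "double")
  nc <- ncdf4::nc_create(path2, list(vu, vv, vt))
  # u varies with latitude so the flip is observable: u = lat value
  u_file <- array(0, c(3, 3, 2, 3)) # (lon, lat, height, time)
  for (la in 1:3) u_file[, la, , ] <- lats_desc[la]
  ncdf4::ncvar_put(nc, vu, u_file)
  ncdf4::ncvar_put(nc, vv, array(0, c(3, 3, 2, 3)))
  ncdf4::ncvar_put(nc, vt, array(293.15, c(3, 3, 2, 3)))
  ncdf4::nc_close(nc)
  g2 <- read_wind_netcdf(path2)
  expect_equal(g2$lats, c(20, 25, 30))
  # after normalization the field still maps latitude -> its own value
  s <- sample_field(g2, g2$times[1], 25, 95, 500)
  expect_equal(s$u, 25)
  expect_equal(s$temperature, 20, tolerance = 1e-9) # 293.15 K -> 20 C
})

test_that("profile export writes one row per height with sampled values", {
  g <- test_grid(u = 3, v = -2, temp = 18)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  prof <- export_profile_csv(g, g$times[2], 24, 98,
                             heights = c(100, 500, 1000), path = path)
  expect_equal(nrow(prof), 3)
  back <- read.csv(path)
  expect_equal(back$u, rep(3, 3))
  expect_equal(back$temperature, rep(18, 3))
})
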