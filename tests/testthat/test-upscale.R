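make_toy_city <- function() {
  pop <- population_raster(matrix(c(100, 0, 50, 250), 2, 2), cellsize = 100)
  labels <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  info <- data.frame(label = 1:2, name = c("A", "B"), area_km2 = c(0.02, 0.02))
  list(pop = pop, districts = district_map(labels, info, cellsize = 100))
}

test_that("district totals convert population x litres to cubic metres", {
  toy <- make_toy_city()
  per_person <- c(spring = 160, summer = 200)
  res <- district_totals(per_person, toy$districts, toy$pop)
  # district A holds 100 persons, B holds 300
  a_spring <- res$volume_m3[res$district == "A" & res$season == "spring"]
  expect_equal(a_spring, 100 * 160 / 1000)
  b_summer <- res$volume_m3[res$district == "B" & res$season == "summer"]
  expect_equal(b_summer, 300 * 200 / 1000)
  # one million people at 160 L/person/season is 160,000 m3
  big <- population_raster(matrix(1e6, 1, 1), cellsize = 100)
  bigd <- district_map(matrix(1L, 1, 1),
                       data.frame(label = 1L, name = "X", area_km2 = 1),
                       cellsize = 100)
  expect_equal(district_totals(c(spring = 160), bigd, big)$volume_m3, 160000)
})

test_that("zero-population districts contribute zero and merging is additive", {
  pop <- population_raster(matrix(c(10, 0, 0, 0), 2, 2), cellsize = 100)
  labels <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  info <- data.frame(label = 1:2, name = c("A", "B"), area_km2 = c(0.02, 0.02))
  d2 <- district_map(labels, info, cellsize = 100)
  res2 <- district_totals(c(s = 100), d2, pop)
  expect_equal(res2$volume_m3[res2$district == "B"], 0)
  merged <- district_map(matrix(1L, 2, 2),
                         data.frame(label = 1L, name = "AB", area_km2 = 0.04),
                         cellsize = 100)
  res1 <- district_totals(c(s = 100), merged, pop)
  expect_equal(sum(res1$volume_m3), sum(res2$volume_m3))
})

test_that("misaligned grids are rejected", {
  toy <- make_toy_city()
  wrong <- district_map(matrix(1L, 3, 3),
                        data.frame(label = 1L, name = "X", area_km2 = 1),
                        cellsize = 100)
  expect_error(district_totals(c(s = 1), wrong, toy$pop), "not aligned")
})

test_that("intensity raster converts cell volumes to mm over the cell area", {
  # 10 m3/year over a 100 m x 100 m cell is exactly 1 mm/year
  pop <- population_raster(matrix(c(100, 0), 1, 2), cellsize = 100)
  r <- intensity_raster(pop, per_person_annual = 100) # 100 L x 100 p = 10 m3
  expect_equal(r$values[1, 1], 1)
  expect_equal(r$values[1, 2], 0)
  # 156 persons at 640 L/person/year on one hectare: 99.84 m3 -> 9.984 mm
  pop2 <- population_raster(matrix(156, 1, 1), cellsize = 100)
  expect_equal(intensity_raster(pop2, 640)$values[1, 1], 9.984)
  # zero exactly where population is zero
  city <- fixture_city()
  ir <- intensity_raster(city$pop, 500)
  expect_identical(ir$values == 0, city$pop$values == 0)
})

test_that("unit-area intensity divides volume by area and rescales to mm", {
  ui <- unit_area_intensity(5075.2, 1)
  expect_equal(ui$m3_per_km2, 5075.2)
  expect_equal(ui$mm, 5.0752)
  expect_equal(unit_area_intensity(0, 10)$mm, 0)
  expect_equal(unit_area_intensity(2 * 5075.2, 2)$m3_per_km2, 5075.2)
  expect_error(unit_area_intensity(1, 0), "positive")
})

test_that("mass is conserved across aggregation routes", {
  city <- fixture_city()
  per_person <- c(spring = 300, summer = 420, autumn = 330, winter = 400)
  res <- district_totals(per_person, city$districts, city$pop)
  annual_l <- sum(per_person)
  total_by_city <- annual_city_total(res)
  # cells -> city directly
  total_by_cells <- sum(city$pop$values) * annual_l / 1000
  expect_equal(total_by_city, total_by_cells, tolerance = 1e-6)
  # intensity route: mm x cell area summed over cells
  ir <- intensity_raster(city$pop, annual_l)
  total_by_intensity <- sum(ir$values) / 1000 * city$pop$cellsize^2
  expect_equal(total_by_intensity, total_by_city, tolerance = 1e-6)
})

test_that("annual total requires all four seasons and ignores their order", {
  toy <- make_toy_city()
  pp <- c(spring = 1, summer = 2, autumn = 3, winter = 4)
  res <- district_totals(pp, toy$districts, toy$pop)
  resr <- district_totals(rev(pp), toy$districts, toy$pop)
  expect_equal(annual_city_total(res), annual_city_total(resr))
  partial <- district_totals(pp[1:3], toy$districts, toy$pop)
  expect_error(annual_city_total(partial), "missing seasons: winter")
})

test_that("volumes scale linearly with the population raster", {
  city <- fixture_city()
  pp <- c(spring = 300, summer = 420, autumn = 330, winter = 400)
  res1 <- district_totals(pp, city$districts, city$pop)
  pop3 <- population_raster(city$pop$values * 3, city$pop$cellsize)
  res3 <- district_totals(pp, city$districts, pop3)
  expect_equal(res3$volume_m3, 3 * res1$volume_m3)
  expect_equal(annual_city_total(res3), 3 * annual_city_total(res1))
})
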