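# PMI shape triples: analytic limits and the triangle constraint

test_that("rigid fixtures land on their analytic PMI vertices", {
  st <- as.data.frame(shapeTriple(
    c("C#CC#C",                  # rod
      "c1ccccc1",                # disc (planar symmetric top)
      "C1C2CC3CC1CC(C2)C3"),     # adamantane: sphere corner
    nConformers = 1))
  rod <- st[1, ]; disc <- st[2, ]; sphere <- st[3, ]
  expect_lt(rod$npr1, 0.05)
  expect_gt(rod$npr2, 0.95)
  expect_equal(disc$npr1, 0.5, tolerance = 0.02)
  expect_equal(disc$npr2, 0.5, tolerance = 0.02)
  expect_gte(sphere$npr1, 0.9)
  expect_gte(sphere$npr2, 0.9)
  # planar symmetric top identity: I3 = I1 + I2
  expect_equal(disc$I3, disc$I1 + disc$I2, tolerance = 0.02 * disc$I3)
})

test_that("the rigid-body triangle constraint holds on a mixed panel", {
  panel <- c("C#CC#C", "c1ccccc1", "C1C2CC3CC1CC(C2)C3", "CCCCCCCC",
             "CC(=O)Oc1ccccc1C(=O)O", "CC1SC(=O)NC1=O", "c1ccc2ccccc2c1")
  st <- as.data.frame(shapeTriple(panel, nConformers = 1))
  ok <- !is.na(st$npr1)
  expect_gte(sum(ok), 6L)
  expect_true(all(st$npr1[ok] + st$npr2[ok] >= 1 - 1e-6))
  expect_true(all(st$npr1[ok] <= st$npr2[ok] + 1e-9))
  expect_true(all(st$npr1[ok] >= 0 & st$npr2[ok] <= 1 + 1e-9))
  expect_true(all(st$I1[ok] <= st$I2[ok] & st$I2[ok] <= st$I3[ok]))
})

test_that("single-heavy-atom input is rejected as shape-unavailable", {
  expect_error(shapeTriple("C"), "at least 2 heavy atoms")
})
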