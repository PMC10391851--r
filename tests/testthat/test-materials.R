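test_that("base table holds the tabulated tissue and implant constants", {
  tab <- base_material_table()
  expect_s3_class(tab, "material_table")
  expect_equal(tab$bone_quality$label, "NBM")
  e <- tab$entries
  expect_equal(e$cortical$young_modulus, 12000)
  expect_equal(e$cortical$poisson_ratio, 0.30)
  expect_equal(e$cancellous$young_modulus, 450)
  expect_equal(e$cancellous$poisson_ratio, 0.25)
  expect_equal(e$bony_endplate$young_modulus, e$cortical$young_modulus)
  expect_equal(e$cartilaginous_endplate$young_modulus, 25)
  expect_equal(e$cartilaginous_endplate$poisson_ratio, 0.40)
  expect_equal(e$annulus$young_modulus, 4.2)
  expect_equal(e$annulus$poisson_ratio, 0.45)
  expect_equal(e$nucleus$young_modulus, 1)
  expect_equal(e$nucleus$poisson_ratio, 0.499) # incompressible limit clamped
  expect_equal(e$titanium$young_modulus, 110000)
  expect_equal(e$titanium$poisson_ratio, 0.36)
  expect_equal(e$peek$young_modulus, 3600)
  expect_equal(e$peek$poisson_ratio, 0.30)
  # posterior-element cartilage is excluded from the default library
  expect_null(e$articular_cartilage)
})

test_that("near-incompressible Poisson ratio is clamped with a warning", {
  expect_warning(m <- material_spec("nucleus", "nucleus", 1, 0.50), "clamped")
  expect_equal(m$poisson_ratio, 0.499)
  expect_error(material_spec("bad", "cortical", -5, 0.3))
  expect_error(material_spec("bad", "cortical", 100, -0.1))
})

test_that("degradation rule round-half-up reproduces every tabulated bone modulus", {
  expect_identical(degraded_modulus(12000, 0.67), 8040)
  expect_identical(degraded_modulus(450, 0.67), 302)   # 301.5 rounds up
  expect_identical(degraded_modulus(450, 0.33), 149)   # 148.5 rounds up
  for (q in c("NBM", "OPA", "OPS")) {
    bq <- bone_quality(q)
    tab <- degrade_for_bone_quality(base_material_table(), q)
    for (role in c("cortical", "cancellous", "bony_endplate")) {
      expect_equal(tab$entries[[role]]$young_modulus,
                   degraded_modulus(12000 * (role != "cancellous") +
                                      450 * (role == "cancellous"),
                                    bq$factors[[role]]),
                   info = paste(q, role))
    }
  }
})

test_that("bone-quality degradation changes only bone moduli", {
  base <- base_material_table()
  opa <- degrade_for_bone_quality(base, "OPA")
  ops <- degrade_for_bone_quality(base, bone_quality("OPS"))
  expect_equal(opa$entries$cortical$young_modulus, 8040)
  expect_equal(opa$entries$cancellous$young_modulus, 302)
  expect_equal(opa$entries$bony_endplate$young_modulus, 8040)
  expect_equal(ops$entries$cortical$young_modulus, 8040)
  expect_equal(ops$entries$cancellous$young_modulus, 149)
  # Poisson ratios and non-bone roles untouched
  for (role in names(base$entries)) {
    expect_equal(ops$entries[[role]]$poisson_ratio,
                 base$entries[[role]]$poisson_ratio)
    if (!role %in% c("cortical", "cancellous", "bony_endplate"))
      expect_equal(ops$entries[[role]]$young_modulus,
                   base$entries[[role]]$young_modulus)
  }
  # identity for NBM, idempotence per quality, input not mutated
  expect_equal(degrade_for_bone_quality(base, "NBM"), base)
  expect_equal(degrade_for_bone_quality(ops, "OPS"), ops)
  expect_equal(base$entries$cortical$young_modulus, 12000)
  expect_error(degrade_for_bone_quality(base, bone_quality("bogus")))
})

test_that("quality factors are in (0,1] and non-increasing NBM -> OPA -> OPS", {
  f <- sapply(c("NBM", "OPA", "OPS"), function(q) bone_quality(q)$factors)
  expect_true(all(f > 0 & f <= 1))
  expect_true(all(f[, "NBM"] == 1))
  expect_true(all(f[, "OPA"] >= f[, "OPS"]))
  expect_true(all(f[, "NBM"] >= f[, "OPA"]))
})

test_that("Lame conversion matches closed forms", {
  expect_equal(lame_parameters(1, 0), c(lambda = 0, mu = 0.5))
  lm <- lame_parameters(12000, 0.30)
  expect_equal(unname(lm["lambda"]), 12000 * 0.3 / (1.3 * 0.4))
  expect_equal(round(unname(lm["lambda"]), 2), 6923.08)
  expect_equal(round(unname(lm["mu"]), 2), 4615.38)
  expect_equal(lame_parameters(450, 0.25), c(lambda = 180, mu = 180))
  expect_equal(lame_parameters(base_material_table()$entries$cancellous),
               c(lambda = 180, mu = 180))
  expect_error(lame_parameters(100, 0.5))
  # positive for nu in (0, 0.5)
  for (nu in c(0.05, 0.25, 0.45, 0.499))
    expect_true(all(lame_parameters(100, nu) > 0))
})

test_that("material table round-trips through YAML bit-exactly", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  for (q in c("NBM", "OPS")) {
    tab <- degrade_for_bone_quality(base_material_table(), q)
    write_material_table(tab, tmp)
    back <- read_material_table(tmp)
    expect_identical(back$bone_quality$label, tab$bone_quality$label)
    for (role in names(tab$entries)) {
      expect_identical(back$entries[[role]]$young_modulus,
                       tab$entries[[role]]$young_modulus)
      expect_identical(back$entries[[role]]$poisson_ratio,
                       tab$entries[[role]]$poisson_ratio)
    }
  }
})
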