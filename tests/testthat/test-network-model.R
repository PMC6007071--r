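test_that("the reaction catalog has the fixed two-site structure", {
  cat <- reaction_catalog()
  expect_equal(nrow(cat), 16)
  expect_setequal(cat$id, phosswitch:::REACTION_IDS)

  # substrate and product differ at exactly one phosphosite
  site_diff <- mapply(function(s, p) {
    sum(strsplit(s, "")[[1]] != strsplit(p, "")[[1]])
  }, cat$substrate, cat$product)
  expect_true(all(site_diff == 1))

  # mechanisms and modifiers follow the family naming
  expect_true(all(cat$catalyst[cat$mechanism == "spontaneous"] %in% NA))
  expect_true(all(cat$catalyst[grepl("^p", cat$id)] == "PP"))
  expect_true(all(cat$catalyst[grepl("^d", cat$id)] == "OO"))
  expect_true(all(cat$modifier[grepl("^b?p", cat$id)] == "nt"))
  expect_true(all(cat$modifier[grepl("^b?d", cat$id)] == "nd"))

  # spot checks against the model equations
  p2 <- cat[cat$id == "p2", ]
  expect_equal(
    unlist(p2[, c("substrate", "product", "catalyst", "modifier")]),
    c(substrate = "PO", product = "PP", catalyst = "PP", modifier = "nt")
  )
  bd1 <- cat[cat$id == "bd1", ]
  expect_equal(bd1$substrate, "PO")
  expect_equal(bd1$product, "OO")
  expect_true(is.na(bd1$catalyst))
  expect_equal(bd1$modifier, "nd")
})

test_that("presets reproduce the published parameter columns", {
  ti <- preset("TI")
  expect_length(ti$active, 16)
  expect_true(all(ti$rates[c("p0", "p1", "p2", "p3", "d0", "d1", "d2", "d3")] == 1))
  expect_true(all(ti$rates[grep("^b", names(ti$rates))] == 0.05))
  expect_equal(ti$tot, 4)
  expect_equal(ti$nd, 2)

  co <- preset("CO")
  expect_setequal(co$active, c("p0", "p3", "d1", "bd2"))
  expect_equal(unname(co$rates[c("p0", "p3", "d1", "bd2")]), c(1, 1, 1, 0.05))
  expect_true(all(co$rates[setdiff(names(co$rates), co$active)] == 0))

  am <- preset("AM")
  expect_setequal(
    am$active,
    c("p0", "p3", "d0", "d3", "bp0", "bp3", "bd0", "bd3")
  )
  so <- preset("SO")
  expect_setequal(so$active, c("p0", "d1", "bp3", "bd2"))
  bd1 <- preset("BD1")
  expect_setequal(bd1$active, setdiff(preset("BP")$active, "bd1"))

  expect_error(preset("XX"), "AM.*TI.*BP.*BD1.*CO.*SO")
  expect_setequal(presets(), c("AM", "TI", "BP", "BD1", "CO", "SO"))
})

test_that("build_rhs matches an independent transcription of the equations", {
  # hand-evaluated point: everything unmodified, no catalyst present, so only
  # the two spontaneous phosphorylations fire: dOO = -(bp0+bp1)*nt*OO = -0.8
  rhs <- build_rhs(sw_model("TI", nt = 2))
  expect_equal(unname(rhs(c(OO = 4, PP = 0, PO = 0))), c(-0.8, 0, 0.4))

  # all rates zero: derivative identically zero
  zero <- sw_model(topology = character(0), name = "null")
  expect_equal(unname(build_rhs(zero)(c(1, 2, 0.5))), c(0, 0, 0))

  # random rates and states against the reference transcription
  set.seed(7)
  for (k in 1:20) {
    r <- stats::setNames(stats::runif(16), phosswitch:::REACTION_IDS)
    m <- sw_model(
      topology = phosswitch:::REACTION_IDS, rates = r,
      tot = 4, nd = stats::runif(1, 0, 3), nt = stats::runif(1, 0, 6)
    )
    s <- random_simplex_points(1, seed = k)[1, ]
    expect_equal(
      unname(build_rhs(m)(s)),
      reference_rhs(r, m$nt, m$nd, m$tot, s),
      tolerance = 1e-12
    )
  }
})

test_that("deactivating a reaction is identical to a zero rate", {
  full <- sw_model("TI", nt = 3)
  dropped <- drop_reactions(full, "p2")
  zeroed <- sw_model(
    topology = setdiff(full$active, "p2"),
    nt = 3
  )
  s <- c(OO = 1, PP = 1.5, PO = 0.5)
  expect_identical(build_rhs(dropped)(s), build_rhs(zeroed)(s))
  expect_equal(dropped$rates, zeroed$rates)
})

test_that("the analytic Jacobian agrees with central differences", {
  set.seed(11)
  for (k in 1:10) {
    r <- stats::setNames(stats::runif(16), phosswitch:::REACTION_IDS)
    m <- sw_model(phosswitch:::REACTION_IDS, rates = r, nt = stats::runif(1, 0, 5))
    s <- random_simplex_points(1, seed = 100 + k)[1, ]
    f <- build_rhs(m)
    Ja <- build_jacobian(m)(s)
    Jf <- phosswitch:::jacobian_fd(f, s, 1e-6 * m$tot)
    expect_equal(Ja, Jf, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("model construction validates its inputs", {
  expect_error(sw_model("TI", rates = c(p9 = 1)), "Unknown rate")
  expect_error(sw_model(c("p0", "zz")), "Unknown reaction id")
  expect_error(sw_model("CO", rates = c(p1 = 0.5)), "inactive")
  expect_error(sw_model("TI", tot = -1), "tot")
  expect_error(drop_paths(sw_model("TI"), "bp0"), "Unknown path")
})

test_that("config files round-trip through YAML and JSON", {
  cfg <- list(
    topology = c("p0", "p3", "d1", "bd2"), rates = list(bd2 = 0.1),
    tot = 4, nd = 2, nt = 3, name = "custom-co"
  )
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    if (ext == "yaml") yaml::write_yaml(cfg, path) else jsonlite::write_json(cfg, path, auto_unbox = TRUE)
    m <- read_model_config(path)
    expect_setequal(m$active, cfg$topology)
    expect_equal(unname(m$rates["bd2"]), 0.1)
    expect_equal(m$nt, 3)
    expect_equal(m$name, "custom-co")
  }
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(topology = "CO", speed = 3), bad)
  expect_error(read_model_config(bad), "Unknown config key")
})

test_that("the catalog exports as machine-readable TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_tsv(path)
  tab <- utils::read.delim(path, na.strings = "-")
  expect_equal(nrow(tab), 16)
  expect_named(tab, c("id", "substrate", "product", "catalyst", "modifier", "mechanism"))
  expect_equal(sum(is.na(tab$catalyst)), 8)
})
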