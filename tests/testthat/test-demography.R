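test_that("time scaling and harmonic-mean Ne follow their closed forms", {
  expect_equal(generationsToYears(100000, 10), 1e6)
  expect_equal(generationsToYears(0, 10), 0)
  # the ~8 Mya mitis/mona autosomal divergence at 10 y/generation
  expect_equal(generationsToYears(800000, 10), 8e6)
  expect_error(generationsToYears(-1, 10), "tGen")

  expect_equal(harmonicMeanNe(data.frame(duration = c(100, 100),
                                         ne = c(2e5, 2e5))), 2e5)
  expect_equal(harmonicMeanNe(data.frame(duration = c(100, 100),
                                         ne = c(1e5, 3e5))),
               200 / (100 / 1e5 + 100 / 3e5))
  expect_error(harmonicMeanNe(data.frame(duration = numeric(),
                                         ne = numeric())), "non-empty")
  # harmonic <= duration-weighted arithmetic mean, over random inputs
  set.seed(1)
  for (i in 1:20) {
    seg <- data.frame(duration = runif(5, 1, 100), ne = runif(5, 1e3, 1e6))
    arith <- sum(seg$duration * seg$ne) / sum(seg$duration)
    expect_lte(harmonicMeanNe(seg), arith)
  }
})

test_that("Y-model derivation quarters Ne, doubles phi with a cap, and round-trips", {
  m <- DemographicModel(
    c(A = 2e5, B = 2e5, AB = 2e5),
    splits = data.frame(time = c(1e5, 1e5), derived = c("A", "B"),
                        ancestral = "AB"),
    pulses = data.frame(time = 5e4, source = "B", dest = "A", phi = 0.004))
  y <- deriveYModel(m)
  expect_equal(ploidyMode(y), "y_linked")
  expect_equal(populations(y)$A$ne, 5e4)
  expect_equal(pulseEvents(y)$phi, 0.008)
  expect_equal(splitEvents(y)$time, splitEvents(m)$time)
  # round trip where no cap was hit
  back <- new("DemographicModel",
              populations = lapply(populations(y), function(ep) {
                ep$ne <- ep$ne * 4; ep
              }),
              splits = splitEvents(y),
              pulses = transform(pulseEvents(y), phi = phi / 2),
              mu = mutationRate(y), genTime = generationTime(y),
              ploidyMode = "autosomal")
  expect_equal(pulseEvents(back)$phi, pulseEvents(m)$phi)
  expect_equal(populations(back)$A$ne, populations(m)$A$ne)
  # cap at 1 with warning
  m2 <- DemographicModel(
    c(A = 2e5, B = 2e5, AB = 2e5),
    splits = data.frame(time = c(1e5, 1e5), derived = c("A", "B"),
                        ancestral = "AB"),
    pulses = data.frame(time = 5e4, source = "B", dest = "A", phi = 0.6))
  expect_warning(y2 <- deriveYModel(m2), "capped")
  expect_equal(pulseEvents(y2)$phi, 1)
  expect_error(deriveYModel(y), "already")
})

test_that("model validation rejects inconsistent histories", {
  # pulse scheduled older than the MRCA of source and destination
  expect_error(DemographicModel(
    c(A = 1e4, B = 1e4, AB = 1e4),
    splits = data.frame(time = c(1e4, 1e4), derived = c("A", "B"),
                        ancestral = "AB"),
    pulses = data.frame(time = 2e4, source = "B", dest = "A", phi = 0.1)),
    "lifespan")
  # split not preceding the ancestor's own split
  expect_error(DemographicModel(
    c(A = 1e4, B = 1e4, C = 1e4, AB = 1e4, ABC = 1e4),
    splits = data.frame(time = c(3e4, 3e4, 2e4, 2e4),
                        derived = c("A", "B", "AB", "C"),
                        ancestral = c("AB", "AB", "ABC", "ABC"))),
    "precede")
  expect_error(DemographicModel(c(A = -5)), "ne > 0")
  expect_error(DemographicModel(
    c(A = 1e4, B = 1e4, AB = 1e4),
    splits = data.frame(time = c(1e4, 1e4), derived = c("A", "B"),
                        ancestral = "AB"),
    pulses = data.frame(time = 5e3, source = "B", dest = "A", phi = 1.2)),
    "phi")
})

test_that("the default guenon model encodes the three calibrated pulses", {
  m <- guenonModel(phi3 = 0.004)
  validateModel(m)
  pu <- pulseEvents(m)
  expect_equal(pu$phi[pu$source == "anc_mitis"], 0.021)
  expect_equal(pu$time[pu$source == "anc_mitis"], 310000)
  expect_equal(pu$phi[pu$source == "cephus"], 0.085)
  expect_equal(pu$time[pu$source == "cephus"], 270000)
  sp <- splitEvents(m)
  dwSplit <- sp$time[sp$derived == "denti"]
  expect_equal(dwSplit, 110000)
  # pulse 3 fires 10,000 generations after the denti/wolfi split
  expect_equal(pu$time[pu$source == "mitis"], dwSplit - 10000)
  expect_equal(mutationRate(m), 4.82e-9)
  expect_equal(generationTime(m), 10)
  expect_equal(populations(m)$denti$ne, 200000)
  # zero-rate pulse is dropped entirely
  expect_equal(nrow(pulseEvents(guenonModel(phi3 = 0))), 2)
})

test_that("the shipped demography config parses into the default model", {
  cfg <- system.file("extdata", "guenon_model.yaml", package = "ygeneflow")
  expect_true(nzchar(cfg))
  m <- readDemographyConfig(cfg)
  expect_true(validateModel(m))
  expect_equal(pulseEvents(m)$phi, pulseEvents(guenonModel())$phi)
  expect_equal(populations(m)$denti$ne, 200000)
})

test_that("config serialization round-trips the default model losslessly", {
  m <- guenonModel(phi3 = 0.0042)
  f <- tempfile(fileext = ".yaml")
  writeDemographyConfig(m, f)
  m2 <- readDemographyConfig(f)
  expect_equal(populations(m2), populations(m))
  expect_equal(splitEvents(m2)$time, splitEvents(m)$time)
  expect_equal(pulseEvents(m2)$phi, pulseEvents(m)$phi)
  expect_equal(mutationRate(m2), mutationRate(m))
  expect_equal(ploidyMode(m2), ploidyMode(m))
  j <- tempfile(fileext = ".json")
  exportModelJson(m, j)
  parsed <- jsonlite::read_json(j)
  expect_equal(parsed$mu, 4.82e-9)
  expect_equal(parsed$splits[[1]]$time_years,
               splitEvents(m)$time[1] * 10)
})
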