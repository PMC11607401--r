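#' DemographicModel: populations, splits and introgression pulses
#'
#' An S4 container for a multispecies demographic history with instantaneous
#' unidirectional introgression pulses, in the multispecies-coalescent-with-
#' introgression (MSci) style. Time is measured backward from the present in
#' generations; years are a reporting conversion only
#' (see [generationsToYears()]).
#'
#' @slot populations Named list; one element per population (terminal or
#'   ancestral), each a data.frame with columns `start`, `end`, `ne` giving
#'   piecewise-constant diploid effective sizes over backward-time epochs
#'   (`end` may be `Inf`).
#' @slot splits data.frame with columns `time`, `derived`, `ancestral`:
#'   backward in time, lineages in `derived` move into `ancestral` at `time`.
#' @slot pulses data.frame with columns `time`, `source`, `dest`, `phi`:
#'   backward in time, each lineage in `dest` relocates to `source` with
#'   probability `phi` at `time` (forward in time: a fraction `phi` of `dest`
#'   descends from `source` migrants).
#' @slot mu Mutation rate, substitutions per bp per generation.
#' @slot genTime Generation time in years.
#' @slot ploidyMode `"autosomal"` or `"y_linked"`. In `y_linked` mode the
#'   stored Ne values are the Y-effective sizes (one quarter of the autosomal
#'   values) and pulse proportions are the male-mediated (doubled) ones; use
#'   [deriveYModel()] to construct such a model.
#'
#' @seealso [guenonModel()], [deriveYModel()], [simulateGeneTree()]
#' @export
setClass("DemographicModel",
  representation(
    populations = "list",
    splits      = "data.frame",
    pulses      = "data.frame",
    mu          = "numeric",
    genTime     = "numeric",
    ploidyMode  = "character"
  )
)

# interval on which a population holds lineages (backward time, half-open)
.popSpan <- function(object, pop) {
  sp <- object@splits
  start <- if (any(sp$ancestral == pop)) max(sp$time[sp$ancestral == pop]) else 0
  end <- if (any(sp$derived == pop)) sp$time[sp$derived == pop][1] else Inf
  c(start = start, end = end)
}

setValidity("DemographicModel", function(object) {
  msgs <- character()
  pops <- names(object@populations)
  if (is.null(pops) || any(pops == "") || anyDuplicated(pops))
    return("populations must be a uniquely named list")
  for (p in pops) {
    ep <- object@populations[[p]]
    if (!all(c("start", "end", "ne") %in% names(ep)) || any(ep$ne <= 0))
      msgs <- c(msgs, sprintf("population '%s': epochs need start/end/ne with ne > 0", p))
  }
  sp <- object@splits
  if (nrow(sp)) {
    if (anyDuplicated(sp$derived))
      msgs <- c(msgs, "a population may split into an ancestor only once")
    bad <- !(c(sp$derived, sp$ancestral) %in% pops)
    if (any(bad)) msgs <- c(msgs, "splits reference unknown populations")
    if (any(sp$time < 0)) msgs <- c(msgs, "split times must be >= 0")
    if (!length(msgs)) {
      for (i in seq_len(nrow(sp))) {
        anc.end <- .popSpan(object, sp$ancestral[i])["end"]
        if (!(sp$time[i] < anc.end))
          msgs <- c(msgs, sprintf(
            "split %s -> %s at %g must precede the ancestral population's own split (%g)",
            sp$derived[i], sp$ancestral[i], sp$time[i], anc.end))
      }
    }
  }
  pu <- object@pulses
  if (nrow(pu) && !length(msgs)) {
    if (any(pu$phi < 0 | pu$phi > 1)) msgs <- c(msgs, "pulse phi must lie in [0, 1]")
    if (!all(c(pu$source, pu$dest) %in% pops))
      msgs <- c(msgs, "pulses reference unknown populations")
    else for (i in seq_len(nrow(pu))) {
      for (role in c("source", "dest")) {
        span <- .popSpan(object, pu[[role]][i])
        if (!(pu$time[i] >= span["start"] && pu$time[i] < span["end"]))
          msgs <- c(msgs, sprintf(
            "pulse at %g references population '%s' outside its lifespan [%g, %g)",
            pu$time[i], pu[[role]][i], span["start"], span["end"]))
      }
    }
  }
  if (length(object@mu) != 1 || object@mu < 0) msgs <- c(msgs, "mu must be a single value >= 0")
  if (length(object@genTime) != 1 || object@genTime <= 0)
    msgs <- c(msgs, "genTime must be a single positive value")
  if (!object@ploidyMode %in% c("autosomal", "y_linked"))
    msgs <- c(msgs, "ploidyMode must be 'autosomal' or 'y_linked'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DemographicModel
#'
#' @param populations Either a named numeric vector of constant diploid Ne
#'   values, or a named list of epoch data.frames (`start`, `end`, `ne`).
#' @param splits data.frame(time, derived, ancestral), times in generations
#'   backward from the present.
#' @param pulses data.frame(time, source, dest, phi); may be empty.
#' @param mu Mutation rate per bp per generation.
#' @param genTime Generation time in years.
#' @param ploidyMode `"autosomal"` (default) or `"y_linked"`.
#' @return A validated [DemographicModel-class] object.
#' @export
#' @examples
#' m <- DemographicModel(
#'   populations = c(A = 1e4, B = 1e4, anc = 2e4),
#'   splits = data.frame(time = c(1e4, 1e4), derived = c("A", "B"),
#'                       ancestral = "anc"),
#'   mu = 1e-8, genTime = 10)
DemographicModel <- function(populations, splits = NULL, pulses = NULL,
                             mu = 4.82e-9, genTime = 10,
                             ploidyMode = "autosomal") {
  if (is.numeric(populations)) {
    populations <- lapply(populations, function(ne)
      data.frame(start = 0, end = Inf, ne = ne))
  }
  if (is.null(splits))
    splits <- data.frame(time = numeric(), derived = character(),
                         ancestral = character())
  if (is.null(pulses))
    pulses <- data.frame(time = numeric(), source = character(),
                         dest = character(), phi = numeric())
  new("DemographicModel",
      populations = populations,
      splits = splits[order(splits$time), , drop = FALSE],
      pulses = pulses[order(pulses$time), , drop = FALSE],
      mu = mu, genTime = genTime, ploidyMode = ploidyMode)
}

setMethod("show", "DemographicModel", function(object) {
  cat(sprintf("DemographicModel (%s): %d populations, %d splits, %d pulses\n",
              object@ploidyMode, length(object@populations),
              nrow(object@splits), nrow(object@pulses)))
  cat(sprintf("  mu = %g /bp/gen, generation time = %g y\n",
              object@mu, object@genTime))
  if (nrow(object@pulses)) {
    for (i in seq_len(nrow(object@pulses)))
      cat(sprintf("  pulse: %s -> %s, phi = %g, t = %g gen\n",
                  object@pulses$source[i], object@pulses$dest[i],
                  object@pulses$phi[i], object@pulses$time[i]))
  }
  invisible(object)
})

#' @rdname accessors
#' @param object A [DemographicModel-class].
#' @export
populations <- function(object) object@populations

#' Model accessors
#'
#' Small read accessors for [DemographicModel-class] slots.
#' @name accessors
#' @return The slot contents.
#' @export
splitEvents <- function(object) object@splits

#' @rdname accessors
#' @export
pulseEvents <- function(object) object@pulses

#' @rdname accessors
#' @export
mutationRate <- function(object) object@mu

#' @rdname accessors
#' @export
generationTime <- function(object) object@genTime

#' @rdname accessors
#' @export
ploidyMode <- function(object) object@ploidyMode

#' Convert backward times from generations to years
#'
#' @param tGen Time(s) in generations (>= 0).
#' @param g Generation time in years (> 0).
#' @return `tGen * g`, in years.
#' @export
#' @examples
#' generationsToYears(100000, 10)  # 1e6 years
generationsToYears <- function(tGen, g) {
  .check(all(tGen >= 0), "tGen must be >= 0")
  .check(length(g) == 1 && g > 0, "g must be a single positive value")
  tGen * g
}

#' Duration-weighted harmonic mean effective population size
#'
#' Collapses a sequence of Ne epochs along a branch path into the single Ne
#' that preserves expected coalescent intensity:
#' `sum(d) / sum(d / ne)`.
#'
#' @param segments data.frame with columns `duration` (generations, > 0) and
#'   `ne` (> 0), or a numeric matrix with those two columns.
#' @return The harmonic-mean Ne (never exceeds the arithmetic mean).
#' @export
#' @examples
#' harmonicMeanNe(data.frame(duration = c(100, 100), ne = c(1e5, 3e5)))
harmonicMeanNe <- function(segments) {
  segments <- as.data.frame(segments)
  if (!all(c("duration", "ne") %in% names(segments)))
    names(segments)[1:2] <- c("duration", "ne")
  .check(nrow(segments) > 0, "segments must be non-empty")
  .check(all(segments$duration > 0), "durations must be > 0")
  .check(all(segments$ne > 0), "ne must be > 0")
  sum(segments$duration) / sum(segments$duration / segments$ne)
}

#' Derive the Y-linked version of an autosomal demographic model
#'
#' Y chromosomes are carried by one quarter as many effective copies as
#' autosomes (Ne_Y / Ne_autosomes = 0.25), and under exclusively male-mediated
#' migration the effective Y migration proportion is twice the autosomal one.
#' Divides every Ne by four and doubles every pulse phi (capped at 1, with a
#' warning); split times are unchanged.
#'
#' @param model An autosomal [DemographicModel-class].
#' @return A `y_linked` [DemographicModel-class].
#' @export
deriveYModel <- function(model) {
  .check(is(model, "DemographicModel"), "model must be a DemographicModel")
  .check(model@ploidyMode == "autosomal", "model is already y_linked")
  pops <- lapply(model@populations, function(ep) {
    ep$ne <- ep$ne / 4
    ep
  })
  pu <- model@pulses
  if (nrow(pu)) {
    doubled <- 2 * pu$phi
    if (any(doubled > 1))
      warning("doubled pulse proportion exceeded 1 and was capped")
    pu$phi <- pmin(doubled, 1)
  }
  new("DemographicModel", populations = pops, splits = model@splits,
      pulses = pu, mu = model@mu, genTime = model@genTime,
      ploidyMode = "y_linked")
}

#' The default guenon demographic model
#'
#' A nine-population model of the focal guenon lineages (the eastern mona
#' clade *C. denti*, *C. wolfi*, *C. pogonias* plus *C. mona*; *C. neglectus*;
#' the cephus lineage; the mitis group *C. nictitans* and *C. mitis
#' opisthostictus*, here `"mitis"`) with the rhesus macaque as outgroup, and
#' three unidirectional introgression pulses:
#'
#' 1. `phi1` (default 2.1%) from the mitis-group ancestor into the ancestor of
#'    denti/wolfi/pogonias at 310,000 generations ago;
#' 2. `phi2` (default 8.5%) from the cephus lineage into the same recipient at
#'    270,000 generations ago;
#' 3. `phi3` (configurable; default 0.2%) from *C. mitis* into *C. denti* at
#'    100,000 generations ago — 10,000 generations after the denti/wolfi
#'    split at 110,000 generations ago.
#'
#' Branch Ne defaults to 200,000 diploids everywhere (overridable); internal
#' split times that the model needs but that are not part of the pulse
#' calibration (macaque root, mona-group and cephus/mitis joins) are
#' package-level defaults chosen so every pulse references populations alive
#' at its time, with the mitis/mona divergence at 800,000 generations
#' (~8 Mya at 10 y/generation).
#'
#' @param phi3 Proportion of the mitis -> denti pulse (the quantity varied in
#'   the migration-rate experiments).
#' @param phi1,phi2 Proportions of the two ancestral pulses.
#' @param ne Diploid Ne used for every branch (single value or named vector
#'   overriding specific populations).
#' @param mu,genTime Mutation rate and generation time.
#' @return An autosomal [DemographicModel-class].
#' @export
#' @examples
#' m <- guenonModel(phi3 = 0.004)
#' pulseEvents(m)
guenonModel <- function(phi3 = 0.002, phi1 = 0.021, phi2 = 0.085,
                        ne = 200000, mu = 4.82e-9, genTime = 10) {
  popNames <- c("denti", "wolfi", "pogonias", "mona", "neglectus", "cephus",
                "nictitans", "mitis", "macaque",
                "anc_dw", "anc_dwp", "anc_mona", "anc_mitis", "anc_cm",
                "anc_cmn", "anc_guenon", "root")
  nes <- setNames(rep(if (length(ne) == 1) ne else 200000, length(popNames)),
                  popNames)
  if (length(ne) > 1) nes[names(ne)] <- ne
  splits <- data.frame(
    time = c(110000, 110000, 200000, 200000, 450000, 450000,
             250000, 250000, 550000, 550000, 650000, 650000,
             800000, 800000, 1350000, 1350000),
    derived = c("denti", "wolfi", "anc_dw", "pogonias", "anc_dwp", "mona",
                "nictitans", "mitis", "anc_mitis", "cephus", "anc_cm",
                "neglectus", "anc_mona", "anc_cmn", "anc_guenon", "macaque"),
    ancestral = c("anc_dw", "anc_dw", "anc_dwp", "anc_dwp", "anc_mona",
                  "anc_mona", "anc_mitis", "anc_mitis", "anc_cm", "anc_cm",
                  "anc_cmn", "anc_cmn", "anc_guenon", "anc_guenon",
                  "root", "root"))
  pulses <- data.frame(
    time = c(310000, 270000, 100000),
    source = c("anc_mitis", "cephus", "mitis"),
    dest = c("anc_dwp", "anc_dwp", "denti"),
    phi = c(phi1, phi2, phi3))
  pulses <- pulses[pulses$phi > 0, , drop = FALSE]
  DemographicModel(nes, splits, pulses, mu = mu, genTime = genTime)
}

#' Validate a demographic model
#'
#' Runs the full S4 validity machinery and returns `TRUE` invisibly or throws
#' an informative error.
#' @param model A [DemographicModel-class].
#' @export
validateModel <- function(model) {
  validObject(model)
  invisible(TRUE)
}

#' Read / write demographic-model configuration files
#'
#' The configuration format is YAML with blocks `populations` (name -> Ne or
#' name -> list of epochs), `splits`, `pulses`, `mu`, `gen_time`,
#' `ploidy_mode`. Round-trips losslessly.
#'
#' @param path Config file path.
#' @return `readDemographyConfig` returns a [DemographicModel-class];
#'   `writeDemographyConfig` returns `path` invisibly.
#' @export
readDemographyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  pops <- lapply(cfg$populations, function(p) {
    if (is.numeric(p) && length(p) == 1)
      data.frame(start = 0, end = Inf, ne = p)
    else {
      d <- do.call(rbind, lapply(p, as.data.frame))
      d$end[is.na(d$end) | d$end == "Inf"] <- Inf
      d
    }
  })
  toDf <- function(x, cols) {
    if (is.null(x) || !length(x))
      return(NULL)
    d <- do.call(rbind, lapply(x, function(r) as.data.frame(r[cols])))
    d
  }
  model <- DemographicModel(
    populations = pops,
    splits = toDf(cfg$splits, c("time", "derived", "ancestral")),
    pulses = toDf(cfg$pulses, c("time", "source", "dest", "phi")),
    mu = cfg$mu, genTime = cfg$gen_time,
    ploidyMode = if (is.null(cfg$ploidy_mode)) "autosomal" else cfg$ploidy_mode)
  validObject(model)
  model
}

#' @rdname readDemographyConfig
#' @param model A [DemographicModel-class] to serialize.
#' @export
writeDemographyConfig <- function(model, path) {
  pops <- lapply(model@populations, function(ep) {
    if (nrow(ep) == 1 && ep$start == 0 && is.infinite(ep$end)) ep$ne
    else lapply(seq_len(nrow(ep)), function(i)
      list(start = ep$start[i],
           end = if (is.infinite(ep$end[i])) "Inf" else ep$end[i],
           ne = ep$ne[i]))
  })
  rows <- function(d) lapply(seq_len(nrow(d)), function(i) as.list(d[i, ]))
  cfg <- list(populations = pops,
              splits = rows(model@splits),
              pulses = rows(model@pulses),
              mu = model@mu, gen_time = model@genTime,
              ploidy_mode = model@ploidyMode)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export a demographic model as JSON
#'
#' Writes the model — with times additionally reported in years — to a JSON
#' file, for interchange with other tools.
#' @param model A [DemographicModel-class].
#' @param path Output file.
#' @export
exportModelJson <- function(model, path) {
  sp <- model@splits
  sp$time_years <- generationsToYears(sp$time, model@genTime)
  pu <- model@pulses
  if (nrow(pu)) pu$time_years <- generationsToYears(pu$time, model@genTime)
  out <- list(
    ploidy_mode = model@ploidyMode, mu = model@mu, gen_time = model@genTime,
    populations = lapply(model@populations, function(ep) {
      ep$end[is.infinite(ep$end)] <- NA
      ep
    }),
    splits = sp, pulses = pu)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

# --- internal: compile a model into integer tables for the C++ engine ------

# events matrix columns: time, type (0 pulse / 1 split / 2 ne-change),
# a, b (0-based pop indices), x (phi or ne)
.compileModel <- function(model) {
  pops <- names(model@populations)
  idx <- setNames(seq_along(pops) - 1L, pops)
  ne0 <- vapply(model@populations, function(ep) {
    ep$ne[which(ep$start <= 0 & ep$end > 0)[1]]
  }, numeric(1))
  ev <- list()
  sp <- model@splits
  if (nrow(sp))
    ev[[length(ev) + 1L]] <- cbind(sp$time, 1, idx[sp$derived],
                                   idx[sp$ancestral], 0)
  pu <- model@pulses
  if (nrow(pu))
    ev[[length(ev) + 1L]] <- cbind(pu$time, 0, idx[pu$source],
                                   idx[pu$dest], pu$phi)
  for (p in pops) {
    ep <- model@populations[[p]]
    if (nrow(ep) > 1) {
      ep <- ep[order(ep$start), ]
      later <- ep[-1, , drop = FALSE]
      ev[[length(ev) + 1L]] <- cbind(later$start, 2, idx[p], 0, later$ne)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    matrix(numeric(), ncol = 5)
  # pulses before splits at identical times (a pulse scheduled exactly at a
  # split must still see the destination's lineages)
  events <- events[order(events[, 1], events[, 2]), , drop = FALSE]
  list(popIndex = idx, ne0 = unname(ne0), events = events)
}
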