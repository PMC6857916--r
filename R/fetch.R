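example_registry <- list(
  titanic = list(
    source = "local", package = "carData", dataset = "TitanicSurvival",
    note = "1309 Titanic passengers: survived, age, passenger class, sex"),
  lung = list(
    source = "local", package = "survival", dataset = "lung",
    data_name = "cancer",
    note = "228 advanced lung cancer patients: time, status, age, wt.loss, ph.ecog, sex"),
  crabs = list(
    source = "url",
    url = "https://raw.githubusercontent.com/cran/glm2/master/data/crabs.rda",
    kind = "rda", object = "crabs",
    note = "173 female horseshoe crabs: satellite counts, width, dark colouring"),
  ragweed = list(
    source = "url",
    url = "https://raw.githubusercontent.com/cran/SemiPar/master/data/ragweed.rda",
    kind = "rda", object = "ragweed",
    note = "ragweed pollen counts with temperature, rain, wind speed, day in season"))

#' Fetch a classic example dataset
#'
#' Returns one of the four worked-example datasets as a typed bundle matching
#' the variable usage of the corresponding published analysis. `titanic`
#' (from the locally installed carData package) and `lung` (from survival)
#' need no network. `crabs` and `ragweed` are downloaded from their CRAN
#' source packages and cached; the checksum of the first successful download
#' is recorded in the cache and verified on every later fetch, and a cached
#' copy is always preferred (no network touched on a cache hit). Offline
#' with a cold cache, fetching fails with a clear error; everything else in
#' the package works without these datasets, which are optional verification
#' material.
#'
#' @param name one of `"titanic"`, `"crabs"`, `"ragweed"`, `"lung"`.
#' @param cache_dir cache directory.
#' @return a `dn_bundle` with `provenance = "fetched"` and the published
#'   model attached as `$formula`.
#' @export
fetch_example <- function(name = c("titanic", "crabs", "ragweed", "lung"),
                          cache_dir = tools::R_user_dir("dynogram", "cache")) {
  name <- match.arg(name)
  reg <- example_registry[[name]]
  raw <- if (reg$source == "local") fetch_local(reg, name)
         else fetch_url(reg, name, cache_dir)
  shape_example(name, raw)
}

fetch_local <- function(reg, name) {
  if (!requireNamespace(reg$package, quietly = TRUE))
    stop("the '", name, "' example needs the ", reg$package,
         " package, which is not installed; these example datasets are ",
         "optional", call. = FALSE)
  env <- new.env()
  utils::data(list = reg$data_name %||% reg$dataset, package = reg$package,
              envir = env)
  get(reg$dataset, envir = env)
}

fetch_url <- function(reg, name, cache_dir) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  cache_file <- file.path(cache_dir, basename(reg$url))
  sum_file <- file.path(cache_dir, paste0(name, ".md5"))
  if (!file.exists(cache_file)) {
    ok <- tryCatch(utils::download.file(reg$url, cache_file, mode = "wb",
                                        quiet = TRUE) == 0,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(cache_file) || file.size(cache_file) == 0) {
      unlink(cache_file)
      stop("cannot download the optional '", name, "' example dataset ",
           "(offline, and no cached copy); tests using it are optional",
           call. = FALSE)
    }
    writeLines(as.character(tools::md5sum(cache_file)), sum_file)
  }
  got <- as.character(tools::md5sum(cache_file))
  if (file.exists(sum_file) && !identical(got, readLines(sum_file)[1]))
    stop("checksum mismatch for cached '", name, "' dataset; delete ",
         cache_file, " to re-fetch", call. = FALSE)
  env <- new.env()
  load(cache_file, envir = env)
  get(reg$object, envir = env)
}

shape_example <- function(name, raw) {
  switch(name,
    titanic = {
      tab <- data.frame(
        survived = as.integer(as.character(raw$survived) == "yes"),
        age = as.numeric(raw$age),
        pclass = as.character(raw$passengerClass),
        sex = as.character(raw$sex),
        stringsAsFactors = FALSE)
      roles <- list(survived = "covariate", age = "covariate",
                    pclass = "factor", sex = "factor")
      keep <- stats::complete.cases(tab)
      specs <- specs_from_data(tab[keep, ], names(tab), roles)
      fml <- model_spec("survived", "binomial",
                        terms = list(term_covariate("age"),
                                     term_factor("pclass"),
                                     term_factor("sex")))
      new_bundle(tab, specs, "fetched", formula = fml)
    },
    lung = {
      tab <- data.frame(
        time = as.numeric(raw$time),
        status = as.numeric(raw$status) - 1,  # 1/2 coding -> 0/1
        age = as.numeric(raw$age),
        wt.loss = as.numeric(raw$wt.loss),
        ph.ecog = as.numeric(raw$ph.ecog),
        sex = ifelse(raw$sex == 1, "male", "female"),
        stringsAsFactors = FALSE)
      roles <- list(time = "time", status = "status", age = "covariate",
                    wt.loss = "covariate", ph.ecog = "covariate",
                    sex = "factor")
      # reference level male, matching the published sex(female) contrast
      lo <- list(sex = c("male", "female"))
      keep <- stats::complete.cases(tab)
      specs <- specs_from_data(tab[keep, ], names(tab), roles, lo)
      fml <- model_spec(family = "cox", time = "time", status = "status",
                        terms = list(term_covariate("age"),
                                     term_covariate("wt.loss"),
                                     term_covariate("ph.ecog"),
                                     term_factor("sex")),
                        level_order = lo)
      new_bundle(tab, specs, "fetched", formula = fml)
    },
    crabs = {
      tab <- data.frame(
        Satellites = as.numeric(raw$Satellites),
        Width = as.numeric(raw$Width),
        Dark = as.character(raw$Dark),
        stringsAsFactors = FALSE)
      roles <- list(Satellites = "covariate", Width = "covariate",
                    Dark = "factor")
      specs <- specs_from_data(tab, names(tab), roles)
      fml <- model_spec("Satellites", "poisson",
                        terms = list(term_covariate("Width"),
                                     term_factor("Dark")))
      new_bundle(tab, specs, "fetched", formula = fml)
    },
    ragweed = {
      tab <- data.frame(
        sqrtragweed = sqrt(as.numeric(raw$ragweed)),
        rain = as.character(raw$rain),
        temperature = as.numeric(raw$temperature),
        wind.speed = as.numeric(raw$wind.speed),
        day.in.seas = as.numeric(raw$day.in.seas),
        stringsAsFactors = FALSE)
      roles <- list(sqrtragweed = "covariate", rain = "factor",
                    temperature = "covariate", wind.speed = "covariate",
                    day.in.seas = "covariate")
      specs <- specs_from_data(tab, names(tab), roles)
      fml <- model_spec("sqrtragweed", "gaussian",
                        terms = list(term_factor("rain"),
                                     term_covariate("temperature"),
                                     term_covariate("wind.speed"),
                                     term_spline("day.in.seas", 5)))
      new_bundle(tab, specs, "fetched", formula = fml)
    })
}
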