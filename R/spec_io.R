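## plain-text serialisation of a model spec: a key=value config file plus
## CSV tables (transitions.csv, costs.csv, utilities.csv, lifetable.csv,
## toxicities.csv, optional uncertainty.csv / placeholders.csv).  Numbers
## are written with 17 significant digits so the round trip is bit-exact.

num <- function(x) sprintf("%.17g", x)

CONFIG_KEYS <- c("horizon_months", "cycle_months", "start_age", "wtp",
                 "discount_costs", "discount_effects", "sbrt_fraction",
                 "repeat_mdt_monthly_prob", "adt_drug_monthly",
                 "strategies", "event_mdt_workup", "event_sbrt_course",
                 "event_surgery_course", "event_repeat_mdt",
                 "event_adt_initiation", "event_first_month_mdt")

#' Write a model specification to a config file plus CSV tables
#'
#' @param spec A `mdt_spec`.
#' @param dir Output directory (created if missing).  Writes `config.txt`,
#'   `transitions.csv`, `costs.csv`, `utilities.csv`, `lifetable.csv`,
#'   `toxicities.csv`, and `uncertainty.csv` / `placeholders.csv` when
#'   present on the spec.
#' @return The path to `config.txt`, invisibly.
#' @seealso [load_model_spec()]
#' @export
write_model_spec <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- spec$costs$events
  kv <- c(
    horizon_months = num(spec$horizon_months),
    cycle_months = num(spec$cycle_months),
    start_age = num(spec$start_age),
    wtp = num(spec$wtp),
    discount_costs = num(spec$discount$costs),
    discount_effects = num(spec$discount$effects),
    sbrt_fraction = num(spec$sbrt_fraction),
    repeat_mdt_monthly_prob = num(spec$repeat_mdt_monthly_prob),
    adt_drug_monthly = num(spec$costs$adt_drug_monthly),
    strategies = paste(spec$strategies, collapse = ","))
  for (nm in names(ev))
    kv[paste0("event_", nm)] <- num(ev[[nm]])
  writeLines(paste0(names(kv), "=", kv), file.path(dir, "config.txt"))

  wcsv <- function(df, name) {
    numcols <- vapply(df, is.numeric, logical(1))
    df[numcols] <- lapply(df[numcols], num)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  wcsv(spec$transitions, "transitions.csv")
  wcsv(spec$costs$state_monthly, "costs.csv")
  u <- spec$utilities
  urows <- if (is.null(u$adt_free_split)) {
    data.frame(state = c("adt_free", "adt", "crpc"),
               utility = c(u$adt_free, u$adt, u$crpc))
  } else {
    data.frame(state = c("adt_free_sbrt", "adt_free_surgery", "adt", "crpc"),
               utility = c(u$adt_free_split$sbrt, u$adt_free_split$surgery,
                           u$adt, u$crpc))
  }
  wcsv(urows, "utilities.csv")
  wcsv(spec$lifetable, "lifetable.csv")
  wcsv(spec$toxicities, "toxicities.csv")
  if (!is.null(spec$uncertainty)) wcsv(spec$uncertainty, "uncertainty.csv")
  if (!is.null(spec$placeholders))
    utils::write.csv(spec$placeholders, file.path(dir, "placeholders.csv"),
                     row.names = FALSE)
  invisible(file.path(dir, "config.txt"))
}

parse_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0))
    stop("malformed config line: ", lines[eq < 0][1L], call. = FALSE)
  keys <- substr(lines, 1L, eq - 1L)
  vals <- substr(lines, eq + 1L, nchar(lines))
  unknown <- setdiff(keys, CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicated config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  stats::setNames(as.list(vals), keys)
}

#' Load a model specification from a config file and CSV tables
#'
#' Reads the format written by [write_model_spec()]; the round trip
#' reproduces the spec exactly.  Unknown config keys are rejected, every
#' invariant is checked after assembly ([validate_spec()] must return zero
#' diagnostics), and active placeholder values trigger one warning.
#'
#' @param config_path Path to `config.txt`.
#' @param tables_dir Directory holding the CSV tables (default: the
#'   config's directory).
#' @return A valid `mdt_spec`.
#' @export
load_model_spec <- function(config_path, tables_dir = dirname(config_path)) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path, call. = FALSE)
  cfg <- parse_config(config_path)
  need <- function(key) {
    if (is.null(cfg[[key]])) stop("missing config key: ", key, call. = FALSE)
    cfg[[key]]
  }
  rcsv <- function(name, required = TRUE) {
    p <- file.path(tables_dir, name)
    if (!file.exists(p)) {
      if (required) stop("table not found: ", p, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(p, stringsAsFactors = FALSE)
  }

  transitions <- rcsv("transitions.csv")
  for (cn in c("start", "end", "prob"))
    transitions[[cn]] <- as.numeric(transitions[[cn]])
  lifetable <- rcsv("lifetable.csv")
  lifetable$age <- as.integer(lifetable$age)
  for (cn in c("qx", "pca_fraction"))
    lifetable[[cn]] <- as.numeric(lifetable[[cn]])
  toxicities <- rcsv("toxicities.csv")
  toxicities$name <- as.character(toxicities$name)
  toxicities$context <- as.character(toxicities$context)
  toxicities$grade <- as.integer(toxicities$grade)
  for (cn in c("prob", "cost", "rate"))
    toxicities[[cn]] <- as.numeric(toxicities[[cn]])
  state_monthly <- rcsv("costs.csv")
  state_monthly$cost <- as.numeric(state_monthly$cost)

  utab <- rcsv("utilities.csv")
  uget <- function(state) {
    i <- match(state, utab$state)
    if (is.na(i)) NA_real_ else utab$utility[i]
  }
  utilities <- if ("adt_free_sbrt" %in% utab$state) {
    list(adt_free_split = list(sbrt = uget("adt_free_sbrt"),
                               surgery = uget("adt_free_surgery")),
         adt = uget("adt"), crpc = uget("crpc"))
  } else {
    list(adt_free = uget("adt_free"), adt = uget("adt"),
         crpc = uget("crpc"))
  }

  events <- list()
  for (key in grep("^event_", names(cfg), value = TRUE))
    events[[sub("^event_", "", key)]] <- as.numeric(cfg[[key]])

  spec <- model_spec(
    transitions = transitions,
    lifetable = lifetable,
    utilities = utilities,
    costs = list(state_monthly = state_monthly,
                 adt_drug_monthly = as.numeric(need("adt_drug_monthly")),
                 events = events),
    toxicities = toxicities,
    discount = list(costs = as.numeric(need("discount_costs")),
                    effects = as.numeric(need("discount_effects"))),
    sbrt_fraction = as.numeric(need("sbrt_fraction")),
    repeat_mdt_monthly_prob = as.numeric(need("repeat_mdt_monthly_prob")),
    horizon_months = as.numeric(need("horizon_months")),
    cycle_months = as.numeric(need("cycle_months")),
    start_age = as.numeric(need("start_age")),
    wtp = as.numeric(need("wtp")),
    uncertainty = rcsv("uncertainty.csv", required = FALSE),
    strategies = strsplit(need("strategies"), ",", fixed = TRUE)[[1L]],
    placeholders = rcsv("placeholders.csv", required = FALSE))

  d <- validate_spec(spec)
  if (nrow(d) > 0L)
    stop("invalid model spec in ", config_path, ": ",
         paste(d$field, d$rule, sep = ": ", collapse = "; "), call. = FALSE)
  if (!is.null(spec$placeholders) && nrow(spec$placeholders) > 0L)
    warning(sprintf(
      "%d placeholder value(s) active in %s; see placeholders.csv",
      nrow(spec$placeholders), config_path), call. = FALSE)
  spec
}
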