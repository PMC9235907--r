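#' Read and write parameter files
#'
#' Parameters travel as headered CSV with columns `parameter`, `value` and
#' `unit`. Writing records full double precision, so
#' `read_deb_params(write_deb_params(p, f))` is an exact round trip.
#' Unknown parameter names and unit mismatches are rejected; missing
#' parameters are filled from the reference values only when
#' `allow_defaults = TRUE`.
#'
#' @param params a [deb_params()]
#' @param path file path
#' @param allow_defaults fill parameters absent from the file from the
#'   reference set
#' @return `write_deb_params()` returns `path` invisibly;
#'   `read_deb_params()` returns a [deb_params()].
#' @export
write_deb_params <- function(params, path) {
  units <- deb_param_units()
  df <- data.frame(parameter = names(params),
                   value = format(unlist(params), digits = 17,
                                  scientific = FALSE, trim = TRUE),
                   unit = unname(units[names(params)]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_deb_params
#' @export
read_deb_params <- function(path, allow_defaults = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parameter", "value")
  if (!all(need %in% names(df)))
    stop("parameter file must have columns 'parameter' and 'value'")
  known <- names(deb_param_defaults())
  bad <- setdiff(df$parameter, known)
  if (length(bad)) stop("unknown parameter name(s) in file: ",
                        paste(bad, collapse = ", "))
  if ("unit" %in% names(df)) {
    units <- deb_param_units()
    mism <- df$parameter[df$unit != units[df$parameter]]
    if (length(mism))
      stop("unit mismatch for parameter(s): ", paste(mism, collapse = ", "))
  }
  missing <- setdiff(known, df$parameter)
  if (length(missing) && !allow_defaults)
    stop("parameter(s) missing from file: ", paste(missing, collapse = ", "),
         " (set allow_defaults = TRUE to fill from the reference values)")
  vals <- as.numeric(df$value)
  names(vals) <- df$parameter
  do.call(deb_params, as.list(vals))
}

#' Read an environment scenario table
#'
#' Delimited text with mandatory header and columns `time_d` plus any of
#' `T_C`, `moisture_pct`, `om_pct`. Tabulated columns are linearly
#' interpolated; missing ones fall back to the supplied constants.
#'
#' @param path CSV path
#' @param T_C,M,OM constants for columns absent from the file
#' @return a [deb_environment()]
#' @export
read_environment_table <- function(path, T_C = 20, M = 20, OM = 4) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  allowed <- c("time_d", "T_C", "moisture_pct", "om_pct")
  bad <- setdiff(names(df), allowed)
  if (length(bad))
    stop("unexpected column(s) in scenario file: ",
         paste(bad, collapse = ", "), " (allowed: ",
         paste(allowed, collapse = ", "), ")")
  if (!"time_d" %in% names(df))
    stop("scenario file lacks the mandatory 'time_d' column")
  if (any(!vapply(df, is.numeric, logical(1))))
    stop("non-numeric values in scenario file")
  deb_environment(T_C = T_C, M = M, OM = OM, table = df)
}

#' Write an observation set to delimited text
#'
#' One CSV per uni-variate dataset (`<dir>/<name>.csv` with columns `x`,
#' `obs`, `weight`) plus a manifest `manifest.csv` (dataset_id, type,
#' observable, file, and scenario constants as `key=value` pairs) and, when
#' present, `zero_variate.csv`.
#'
#' @param obs an [observation_set()]
#' @param dir output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
write_observation_set <- function(obs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list()
  for (d in obs$datasets) {
    f <- file.path(dir, paste0(d$name, ".csv"))
    utils::write.csv(data.frame(x = d$x, obs = d$obs, weight = d$weights),
                     f, row.names = FALSE)
    sc <- if (length(d$scenario))
      paste(names(d$scenario),
            vapply(d$scenario,
                   function(v) paste(format(v, digits = 17), collapse = "|"),
                   ""),
            sep = "=", collapse = ";")
    else ""
    man[[length(man) + 1]] <- data.frame(
      dataset_id = d$name, type = "uni", observable = d$observable,
      file = basename(f), scenario = sc)
  }
  if (!is.null(obs$zero_variate)) {
    utils::write.csv(obs$zero_variate, file.path(dir, "zero_variate.csv"),
                     row.names = FALSE)
    man[[length(man) + 1]] <- data.frame(
      dataset_id = "zero_variate", type = "zero", observable = "",
      file = "zero_variate.csv", scenario = "")
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, man), mp, row.names = FALSE)
  invisible(mp)
}

#' Read an observation set written by [write_observation_set()]
#'
#' @param dir directory containing `manifest.csv`
#' @return an [observation_set()]
#' @export
read_observation_set <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) stop("no manifest.csv in ", dir)
  man <- utils::read.csv(mp, stringsAsFactors = FALSE)
  zv <- NULL; ds <- list()
  for (i in seq_len(nrow(man))) {
    if (man$type[i] == "zero") {
      zv <- utils::read.csv(file.path(dir, man$file[i]),
                            stringsAsFactors = FALSE)
    } else {
      tab <- utils::read.csv(file.path(dir, man$file[i]))
      sc <- list()
      if (nzchar(man$scenario[i])) {
        for (kv in strsplit(man$scenario[i], ";", fixed = TRUE)[[1]]) {
          parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
          val <- strsplit(parts[2], "|", fixed = TRUE)[[1]]
          num <- suppressWarnings(as.numeric(val))
          sc[[parts[1]]] <- if (any(is.na(num))) val else num
        }
      }
      ds[[length(ds) + 1]] <- deb_dataset(man$dataset_id[i],
                                          man$observable[i],
                                          tab$x, tab$obs, tab$weight, sc)
    }
  }
  observation_set(zero_variate = zv, datasets = ds)
}
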