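# Readers and writers. CSV is the canonical interchange (one row per color
# token); JSON is the nested dialect (trials with token lists). All outputs
# are plain text.

#' Write a game log
#'
#' @param log a [game_log()].
#' @param path output file.
#' @param dialect `"csv"` (one row per token, with `pair_id` and
#'   `condition` columns) or `"json"` (tokens nested under trials).
#' @return `path`, invisibly.
#' @export
write_game_log <- function(log, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(log, "game_log"))
  if (dialect == "csv") {
    out <- cbind(data.frame(pair_id = log$pair_id, condition = log$condition),
                 log$tokens)
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    trials <- lapply(split(log$tokens, log$tokens$turn), function(tr) {
      list(turn = tr$turn[1], sender_id = tr$sender_id[1],
           referent_id = tr$referent_id[1],
           guess_id = if (is.na(tr$guess_id[1])) NULL else tr$guess_id[1],
           correct = tr$correct[1],
           tokens = tr[, c("token_index", "x", "y", "r", "g", "b")])
    })
    names(trials) <- NULL
    jsonlite::write_json(list(pair_id = log$pair_id,
                              condition = log$condition,
                              trials = trials),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read and validate a game log
#'
#' Applies the full structural validation of [validate_tokens()]; schema
#' violations raise errors naming the offending rows. Logged data may use
#' either y-axis convention; `y_origin = "top"` flips y so that the
#' in-memory convention is always bottom-left origin.
#'
#' @param path file written by [write_game_log()] (or matching its schema).
#' @param dialect `"csv"` or `"json"`; default guesses from the extension.
#' @param y_origin `"bottom"` (native) or `"top"` (flip `y` to `1 - y`).
#' @return A validated [game_log()].
#' @export
read_game_log <- function(path, dialect = NULL,
                          y_origin = c("bottom", "top")) {
  y_origin <- match.arg(y_origin)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dialect <- dialect %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  if (dialect == "csv") {
    raw <- utils::read.csv(path)
    missing_cols <- setdiff(c("pair_id", "condition", token_columns()),
                            names(raw))
    if (length(missing_cols)) {
      stop("log missing column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    pair_id <- raw$pair_id[1]
    condition <- as.character(raw$condition[1])
    tokens <- raw[, token_columns()]
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pair_id <- obj$pair_id
    condition <- obj$condition
    trials <- obj$trials
    tokens <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
      tk <- trials$tokens[[i]]
      data.frame(turn = trials$turn[i], sender_id = trials$sender_id[i],
                 referent_id = trials$referent_id[i],
                 token_index = tk$token_index,
                 x = tk$x, y = tk$y, r = tk$r, g = tk$g, b = tk$b,
                 guess_id = if (is.null(trials$guess_id)) NA_integer_
                            else trials$guess_id[i],
                 correct = trials$correct[i])
    }))
  }
  tokens$correct <- as.logical(tokens$correct)
  if (y_origin == "top") tokens$y <- 1 - tokens$y
  game_log(tokens, pair_id = pair_id, condition = condition)
}

flatten_for_output <- function(x) {
  # reduce battery entries to writable tables / scalars
  if (is.data.frame(x)) return(x)
  if (inherits(x, "trend_fit")) {
    if (inherits(x, "trend_fit_failure")) {
      return(data.frame(error = x$error))
    }
    co <- x$coefficients
    co$formula <- deparse1(x$formula)
    co$converged <- x$converged
    co$singular <- x$singular
    co$reduced <- x$reduced
    co$n_obs <- x$n_obs
    return(co)
  }
  if (inherits(x, "battery_failure")) return(data.frame(error = x$error))
  if (is.list(x)) return(lapply(x, flatten_for_output))
  x
}

#' Write a results bundle with a provenance manifest
#'
#' Data frames become CSV files; nested lists are flattened one level with
#' `_`-joined names; scalars and small lists are collected into a JSON
#' sidecar. A `manifest.json` records every emitted file with its MD5
#' hash, the seed, the configuration, and the package version, so a run is
#' reproducible from its manifest alone.
#'
#' @param bundle named list (e.g., a [report()] result).
#' @param out_dir output directory, created if needed.
#' @param seed seed used to produce the bundle.
#' @param config named list of configuration values to record.
#' @return The manifest, invisibly.
#' @export
write_results <- function(bundle, out_dir, seed = NULL, config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  scalars <- list()
  emit <- function(name, obj) {
    obj <- flatten_for_output(obj)
    if (is.data.frame(obj)) {
      f <- file.path(out_dir, paste0(name, ".csv"))
      utils::write.csv(obj, f, row.names = FALSE)
      files <<- c(files, f)
    } else if (is.list(obj)) {
      nested_df <- vapply(obj, is.data.frame, logical(1))
      for (nm in names(obj)[nested_df]) emit(paste0(name, "_", nm), obj[[nm]])
      rest <- obj[!nested_df]
      if (length(rest)) scalars[[name]] <<- rest
    } else {
      scalars[[name]] <<- obj
    }
  }
  for (nm in names(bundle)) emit(nm, bundle[[nm]])
  if (length(scalars)) {
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(scalars, f, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    files <- c(files, f)
  }
  manifest <- list(
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))),
    seed = seed,
    config = config,
    package_version = as.character(utils::packageVersion("dispersim")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
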