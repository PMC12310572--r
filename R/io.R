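#' Read game parameters from a YAML or JSON file
#'
#' The file must hold a flat name-to-value map with exactly the 14 symbol
#' names of [param_names()] (a top-level `params` key wrapping the map is
#' also accepted, as written by [write_game_params()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [game_params()] object.
#' @export
read_game_params <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("parameter file not found: ", path), class = "trigame_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$params)) raw <- raw$params
  validate_parameters(unlist(raw))
}

#' Write game parameters to a YAML or JSON file
#'
#' @param params A [game_params()] object.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @param seed Optional seed to record alongside the parameters.
#' @return The path, invisibly.
#' @export
write_game_params <- function(params, path, seed = NULL) {
  params <- as_game_params(params)
  payload <- list(tool = "trigame",
                  version = as.character(packageVersion("trigame")),
                  params = as.list(unclass(params)))
  if (!is.null(seed)) payload$seed <- seed
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' Plain CSV with header `t,x,y,z`, preceded by `#`-comment provenance lines
#' (tool version and the resolved parameter set) that `read.csv(comment.char
#' = "#")` skips.
#'
#' @param traj A `game_trajectory` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!inherits(traj, "game_trajectory")) {
    abort("traj must be a game_trajectory", class = "trigame_validation_error")
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot write to ", path, ": ", conditionMessage(e)),
          class = "trigame_io_error")
  })
  on.exit(close(con))
  writeLines(c(
    paste0("# trigame ", packageVersion("trigame")),
    paste0("# params: ",
           paste(names(traj$params), unclass(traj$params), sep = "=",
                 collapse = " "))
  ), con)
  utils::write.table(traj$path, con, sep = ",", row.names = FALSE,
                     col.names = c("t", "x", "y", "z"), quote = FALSE)
  invisible(path)
}

result_payload <- function(result) {
  v <- as.character(packageVersion("trigame"))
  if (inherits(result, "game_trajectory")) {
    list(tool = "trigame", version = v, kind = "trajectory",
         params = as.list(unclass(result$params)),
         settings = unclass(result$settings),
         converged = result$converged,
         limit_vertex = if (result$converged) result$limit_vertex else NULL,
         final_state = as.list(tail(result$path, 1)))
  } else if (inherits(result, "game_ess")) {
    list(tool = "trigame", version = v, kind = "ess_report",
         params = as.list(unclass(result$params)), tol = result$tol,
         note = paste("labels follow the E1..E8 vertex convention;",
                      "(0,1,0) is E3 here even where sweep headers call it E2"),
         profiles = lapply(seq_len(nrow(result$table)), function(i) {
           r <- result$table[i, ]
           list(label = r$label, coordinates = c(r$x, r$y, r$z),
                eigenvalues = c(r$lambda1, r$lambda2, r$lambda3),
                classification = r$classification)
         }),
         inequalities = result$conditions)
  } else if (inherits(result, "game_sweep")) {
    list(tool = "trigame", version = v, kind = "sweep",
         base_params = as.list(unclass(result$base_params)),
         settings = unclass(result$settings),
         initial = as.list(result$initial),
         records = result$table)
  } else if (inherits(result, "game_sweep_suite")) {
    list(tool = "trigame", version = v, kind = "sweep_suite",
         base_params = as.list(unclass(attr(result, "base_params"))),
         sweeps = lapply(unclass(result), function(s) s$table))
  } else if (inherits(result, "scenario_set")) {
    list(tool = "trigame", version = v, kind = "scenario_set",
         regime = result$regime, seed = result$seed,
         ranges = result$ranges,
         parameter_sets = lapply(result$params_list,
                                 function(p) as.list(unclass(p))))
  } else if (inherits(result, "game_multistart")) {
    list(tool = "trigame", version = v, kind = "multi_start",
         params = as.list(unclass(result$params)),
         summary = result$summary, starts = result$starts)
  } else {
    list(tool = "trigame", version = v, kind = "generic", value = result)
  }
}

#' Write a result object to disk
#'
#' JSON serialization (full float precision, round-trippable) for any result
#' object of the package, or `t,x,y,z` CSV for trajectories.
#'
#' @param result A result object (`game_trajectory`, `game_ess`,
#'   `game_sweep`, `game_sweep_suite`, `scenario_set`, `game_multistart`).
#' @param path Output path.
#' @param format `"json"` (default) or `"csv"` (trajectories and sweep tables
#'   only).
#' @return The path, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("output directory does not exist: ", dir),
          class = "trigame_io_error")
  }
  if (format == "csv") {
    if (inherits(result, "game_trajectory")) {
      return(write_trajectory_csv(result, path))
    }
    tab <- if (inherits(result, c("game_sweep", "game_sweep_suite"))) {
      tidy(result)
    } else {
      abort("csv output supports trajectories and sweeps only",
            class = "trigame_validation_error")
    }
    ok <- tryCatch({
      utils::write.csv(tab, path, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) abort(paste0("cannot write to ", path), class = "trigame_io_error")
    return(invisible(path))
  }
  payload <- result_payload(result)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "rows", null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write to ", path), class = "trigame_io_error")
  invisible(path)
}
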