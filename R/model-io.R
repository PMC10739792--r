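# File formats: the YAML model dialect, OpenSim-style .sto/.mot motion
# tables, plain-CSV motion tables, and run manifests.

#' Write a walker model definition to a YAML file
#'
#' The on-disk dialect is structured key-value YAML with a `format_version`
#' field; numeric precision is 15 significant digits so a read/write
#' round-trip is lossless at double precision for practical purposes.
#'
#' @param model a `walker_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  as_plain <- function(df) lapply(seq_len(nrow(df)), function(i)
    lapply(as.list(df[i, , drop = FALSE]), function(v)
      if (is.factor(v)) as.character(v) else unname(v)))
  doc <- list(
    format_version = model$format_version,
    segments = as_plain(model$segments),
    joints = as_plain(model$joints),
    muscles = lapply(model$muscles, function(m) list(
      name = m$name, group = m$group,
      params = unclass(m$params),
      path = as_plain(m$path))),
    contact_spheres = as_plain(model$contact_spheres),
    effectors = as_plain(model$effectors),
    options = lapply(model$options, function(o)
      if (is.numeric(o) && !is.null(names(o))) as.list(o) else o),
    standing_height = model$standing_height)
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Read a walker model definition from a YAML file
#'
#' @param path model file (see [write_model()] for the dialect).
#' @return a validated `walker_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse model file ", path, ": ", conditionMessage(e)))
  if (is.null(doc$format_version)) stop("model file lacks format_version")
  as_df <- function(rows) do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  opts <- doc$options
  opts$curve_constants <- unlist(opts$curve_constants)
  model <- structure(list(
    format_version = as.integer(doc$format_version),
    segments = as_df(doc$segments),
    joints = as_df(doc$joints),
    muscles = setNames(lapply(doc$muscles, function(m) list(
      name = m$name, group = m$group,
      params = do.call(mtu_params, m$params),
      path = as_df(m$path))), vapply(doc$muscles, `[[`, character(1), "name")),
    contact_spheres = as_df(doc$contact_spheres),
    effectors = as_df(doc$effectors),
    options = opts,
    standing_height = doc$standing_height),
    class = "walker_model")
  validate_model(model)
  model
}

validate_motion_table <- function(tb, path, activation = FALSE) {
  if (!"time" %in% names(tb)) stop(path, ": no time column")
  if (nrow(tb) >= 2) {
    dt <- diff(tb$time)
    if (any(dt <= 0))
      stop(path, ": non-monotonic time at data row ", which(dt <= 0)[1] + 1)
    if (max(abs(dt - dt[1])) > 1e-6)
      stop(path, ": non-uniform time grid at data row ",
           which(abs(dt - dt[1]) > 1e-6)[1] + 1)
  }
  if (any(!is.finite(as.matrix(tb))))
    stop(path, ": missing or non-finite cells")
  if (activation) {
    vals <- as.matrix(tb[setdiff(names(tb), "time")])
    if (any(vals < 0 | vals > 1))
      stop(path, ": activation values outside [0, 1]")
  }
  tb
}

#' Read a motion or activation table
#'
#' Supports the OpenSim-style `.sto`/`.mot` storage dialect (key=value
#' header terminated by `endheader`, tab/space-separated columns, the
#' `inDegrees` flag honoured) and plain CSV. Angles are converted to radians
#' internally; the time grid must be strictly increasing and uniform.
#'
#' @param path input file.
#' @param dialect `"auto"` (by extension), `"sto_mot"` or `"csv"`.
#' @param activation validate columns as activations in `[0, 1]`.
#' @return data frame with `time` plus named columns.
#' @export
read_motion <- function(path, dialect = c("auto", "sto_mot", "csv"),
                        activation = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("motion file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(sto|mot)$", path, ignore.case = TRUE))
      "sto_mot" else "csv"
  if (dialect == "csv") {
    tb <- tryCatch(read.csv(path, check.names = FALSE),
                   error = function(e) stop(path, ": ", conditionMessage(e)))
    if (nrow(tb) == 0) stop(path, ": empty table")
    return(validate_motion_table(tb, path, activation))
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(path, ": empty file")
  endh <- grep("^\\s*endheader\\s*$", lines)
  if (!length(endh)) stop(path, ": no 'endheader' line")
  header <- lines[seq_len(endh[1] - 1)]
  in_deg <- any(grepl("^\\s*inDegrees\\s*=\\s*yes", header, ignore.case = TRUE))
  body <- lines[(endh[1] + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop(path, ": no data rows")
  cols <- strsplit(trimws(body[1]), "[\t ]+")[[1]]
  rows <- strsplit(trimws(body[-1]), "[\t ]+")
  nbad <- which(vapply(rows, length, integer(1)) != length(cols))
  if (length(nbad))
    stop(path, ": ragged row at line ", endh[1] + 1 + nbad[1])
  M <- matrix(as.numeric(unlist(rows)), ncol = length(cols), byrow = TRUE)
  if (any(!is.finite(M))) stop(path, ": non-numeric cell")
  tb <- as.data.frame(M)
  names(tb) <- cols
  if (in_deg) {
    ang <- setdiff(cols, "time")
    tb[ang] <- tb[ang] * pi / 180
  }
  validate_motion_table(tb, path, activation)
}

#' Write a motion or activation table
#'
#' @param table data frame with `time` plus named columns (angles in rad).
#' @param path output path.
#' @param dialect `"auto"`, `"sto_mot"` or `"csv"`.
#' @param in_degrees write the sto/mot dialect in degrees (the common
#'   convention for .mot joint-angle files).
#' @return `path`, invisibly.
#' @export
write_motion <- function(table, path, dialect = c("auto", "sto_mot", "csv"),
                         in_degrees = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(sto|mot)$", path, ignore.case = TRUE))
      "sto_mot" else "csv"
  if (dialect == "csv") {
    write.csv(table, path, row.names = FALSE)
    return(invisible(path))
  }
  out <- table
  if (in_degrees) {
    ang <- setdiff(names(out), "time")
    out[ang] <- out[ang] * 180 / pi
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(basename(path),
               "version=1",
               paste0("nRows=", nrow(out)),
               paste0("nColumns=", ncol(out)),
               paste0("inDegrees=", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(out), collapse = "\t")), con)
  writeLines(apply(format(out, digits = 12, scientific = FALSE,
                          trim = TRUE), 1,
                   paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of the configuration, seed and package version of a pipeline
#' run, written next to its outputs.
#'
#' @param path output path (.json).
#' @param command the pipeline stage name.
#' @param config named list of configuration values.
#' @param seed the seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seed = NULL) {
  jsonlite::write_json(list(command = command, config = config, seed = seed,
                            package = "planargait",
                            version = as.character(packageVersion("planargait")),
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
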