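#' Read and write motion-parameter files
#'
#' Parameter sets travel as JSON documents of the form
#' ```
#' {"frequency_MHz": 25,
#'  "motions": [{"tau0_s": 4.45e-12, "ea_kJ_per_mol": 12.77,
#'               "dm2_G2": 0.036}, ...]}
#' ```
#' The reader validates motion invariants; the writer emits full double
#' precision so that a write/read round-trip is lossless.
#'
#' @param path File path.
#' @return `read_params()` returns a [relaxation_model()].
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(doc$motions)) stop("parameter file has no 'motions' field: ", path)
  freq <- if (is.null(doc$frequency_MHz)) 25 else doc$frequency_MHz
  motions <- lapply(doc$motions, function(m) {
    need <- c("tau0_s", "ea_kJ_per_mol", "dm2_G2")
    miss <- setdiff(need, names(m))
    if (length(miss))
      stop("motion entry missing field(s) ", paste(miss, collapse = ", "),
           " in ", path)
    motion(m$tau0_s, m$ea_kJ_per_mol, m$dm2_G2)
  })
  relaxation_model(motions, spectrometer_config(freq))
}

#' @rdname read_params
#' @param model A [relaxation_model()] to serialize.
#' @export
write_params <- function(model, path) {
  stopifnot(inherits(model, "relaxation_model"))
  doc <- list(
    frequency_MHz = model$config$frequency_mhz,
    motions = lapply(model$motions, function(m)
      list(tau0_s = m$tau0, ea_kJ_per_mol = m$ea, dm2_G2 = m$dm2)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Sniff the delimiter of a small tabular text file: tab wins if present in
# the header, else comma, else whitespace.
.sniff_sep <- function(path) {
  hdr <- readLines(path, n = 25L)
  hdr <- hdr[!startsWith(hdr, "#")]
  if (length(hdr) == 0L) stop("no tabular content in ", path)
  if (grepl("\t", hdr[1])) "\t" else if (grepl(",", hdr[1])) "," else ""
}

.read_table_checked <- function(path, required, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(label, " file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(label, " file ", path, " has unknown column(s) ignored: ",
            paste(extra, collapse = ", "))
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(label, " file ", path, ": non-numeric value in column '", col,
           "' at data row ", bad)
    }
  }
  df[required]
}

#' Read and write T1-series files
#'
#' Series files are TSV or CSV (auto-detected) with header columns
#' `temperature_K` and `t1_s`, optionally `t1_se_s`. Lines starting with
#' `#` are comments.
#'
#' @param path File path.
#' @return `read_series()` returns a [t1_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path)
  hdr <- readLines(path, n = 25L)
  has_se <- any(grepl("t1_se_s", hdr))
  cols <- c("temperature_K", "t1_s", if (has_se) "t1_se_s")
  df <- .read_table_checked(path, cols, "series")
  t1_series(df$temperature_K, df$t1_s,
            if (has_se) df$t1_se_s else NULL)
}

#' @rdname read_series
#' @param series A [t1_series()] to write.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "t1_series"))
  df <- as.data.frame(series)
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write recovery-curve files
#'
#' Curve files are TSV or CSV with columns `time_s` and `magnetization`;
#' the temperature rides in a comment line `# temperature_K=<value>` or is
#' supplied by the caller (a sidecar manifest, say).
#'
#' @param path File path.
#' @param temperature Temperature in Kelvin, overriding any header comment.
#' @return `read_curve()` returns a [recovery_curve()].
#' @export
read_curve <- function(path, temperature = NULL) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  if (is.null(temperature)) {
    hdr <- grep("^#\\s*temperature_K\\s*=", readLines(path, n = 25L),
                value = TRUE)
    if (length(hdr) == 0L)
      stop("curve file ", path, " carries no '# temperature_K=' line and ",
           "no temperature was supplied")
    temperature <- as.numeric(sub("^#\\s*temperature_K\\s*=\\s*", "", hdr[1]))
  }
  df <- .read_table_checked(path, c("time_s", "magnetization"), "curve")
  recovery_curve(temperature, df$time_s, df$magnetization)
}

#' @rdname read_curve
#' @param curve A [recovery_curve()] to write.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "recovery_curve"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# temperature_K=%.17g", attr(curve, "temperature")), con)
  df <- as.data.frame(curve)
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged reference parameter sets
#'
#' Activation-parameter sets for the internal motions of crystalline
#' magnolol (MAG) and honokiol (HON), unirradiated and after a 400 kGy
#' electron-beam dose, as determined by BPP analysis of 25 MHz T1
#' relaxometry. These are the reference models used throughout the
#' package's parameter-recovery experiments and examples.
#'
#' @param name One of `"mag_0kGy"`, `"mag_400kGy"`, `"hon_0kGy"`,
#'   `"hon_400kGy"`.
#' @return A [relaxation_model()].
#' @examples
#' reference_model("mag_0kGy")
#' @export
reference_model <- function(name = c("mag_0kGy", "mag_400kGy",
                                     "hon_0kGy", "hon_400kGy")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"), package = "bppfit",
                      mustWork = TRUE)
  read_params(path)
}

#' Packaged EPR amplitude table
#'
#' Signal amplitudes of the radiation-induced EPR lines of HON and MAG,
#' shortly after irradiation and after three months of storage, for doses
#' of 0, 25, 100 and 400 kGy.
#'
#' @return An [amplitude_records()] data.frame (8 rows).
#' @export
reference_epr_amplitudes <- function() {
  path <- system.file("extdata", "epr_amplitudes.tsv", package = "bppfit",
                      mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  amplitude_records(df$compound, df$dose_kGy, df$amplitude_initial,
                    df$amplitude_3m)
}
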