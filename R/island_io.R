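#' Read and write island datasets
#'
#' JSON is the canonical on-disk format; a DAISIE-style tab-separated
#' colonization table is provided for interoperability. Ages survive a
#' write/read round trip to full double precision.
#'
#' @param path File path.
#' @param format `"json"` (default) or `"tsv"`.
#' @return `read_island_dataset()` returns an [island_dataset()];
#'   `write_island_dataset()` returns `path` invisibly.
#'
#' @details The JSON schema is
#'   `{island_age, M, clades:[{name, mainland_species_id, status,
#'   colonization_age, branching_ages:[...]}]}`, all ages in My.
#'
#'   The TSV format has comment headers `# island_age=<x>` and `# M=<n>`
#'   followed by a table with columns `clade_name`, `mainland_species_id`,
#'   `status`, `missing_species` (fixed at 0: the models assume complete
#'   sampling) and `branching_times`, the latter a comma-separated list whose
#'   first entry is the colonization age.
#' @examples
#' path <- system.file("extdata", "five_clade_synthetic.json",
#'                     package = "islandDD")
#' ds <- read_island_dataset(path)
#' total_species(ds)
#' @export
read_island_dataset <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") read_island_json(path) else read_island_tsv(path)
}

#' @rdname read_island_dataset
#' @param ds An [island_dataset()].
#' @export
write_island_dataset <- function(ds, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stop_if_invalid(ds)
  if (format == "json") {
    obj <- list(
      island_age = ds$island_age,
      M = ds$M,
      clades = lapply(ds$clades, function(cl) {
        list(name = cl$name,
             mainland_species_id = cl$mainland_species_id,
             status = cl$status,
             colonization_age = cl$colonization_age,
             branching_ages = as.list(cl$branching_ages))
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# island_age=%.15g", ds$island_age),
                 sprintf("# M=%d", ds$M),
                 paste("clade_name", "mainland_species_id", "status",
                       "missing_species", "branching_times", sep = "\t")), con)
    for (cl in ds$clades) {
      times <- paste(sprintf("%.15g", c(cl$colonization_age, cl$branching_ages)),
                     collapse = ",")
      writeLines(paste(cl$name, cl$mainland_species_id, cl$status, 0L, times,
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

read_island_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse JSON dataset '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  for (field in c("island_age", "M")) {
    if (is.null(obj[[field]])) {
      stop("JSON dataset '", path, "' is missing required field '", field, "'",
           call. = FALSE)
    }
  }
  clades <- lapply(seq_along(obj$clades), function(i) {
    cl <- obj$clades[[i]]
    for (field in c("name", "mainland_species_id", "status", "colonization_age")) {
      if (is.null(cl[[field]])) {
        stop("JSON dataset '", path, "', clade ", i,
             ": missing field '", field, "'", call. = FALSE)
      }
    }
    clade_record(cl$name, cl$mainland_species_id, cl$status,
                 cl$colonization_age, unlist(cl$branching_ages))
  })
  ds <- island_dataset(obj$island_age, obj$M, clades, validate = FALSE)
  stop_if_invalid(ds)
  ds
}

read_island_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- regmatches(hdr, regexec(paste0("^#\\s*", key, "\\s*=\\s*(\\S+)"), hdr))
    val <- unlist(lapply(m, function(x) if (length(x) == 2) x[2] else NULL))
    if (!length(val)) stop("TSV dataset '", path, "' is missing '# ", key,
                           "=' header", call. = FALSE)
    as.numeric(val[[1]])
  }
  island_age <- get_hdr("island_age")
  M <- get_hdr("M")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("TSV dataset '", path, "' has no table", call. = FALSE)
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("clade_name", "mainland_species_id", "status", "branching_times")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("TSV dataset '", path, "' lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  clades <- lapply(seq_len(nrow(tab)), function(i) {
    times <- as.numeric(strsplit(as.character(tab$branching_times[i]), ",")[[1]])
    if (!length(times) || any(is.na(times))) {
      stop("TSV dataset '", path, "' line for clade '", tab$clade_name[i],
           "': cannot parse branching_times", call. = FALSE)
    }
    clade_record(tab$clade_name[i], tab$mainland_species_id[i], tab$status[i],
                 times[1], times[-1])
  })
  ds <- island_dataset(island_age, M, clades, validate = FALSE)
  stop_if_invalid(ds)
  ds
}
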