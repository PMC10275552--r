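#' A single island colonist clade
#'
#' One record of the data the likelihood consumes: a mainland species that
#' colonized the island, the age of the colonization (the clade's stem age)
#' and the branching ages of its reconstructed island radiation. All ages are
#' in My before present (present = 0).
#'
#' @param name Text label for the clade.
#' @param mainland_species_id Integer identifier of the mainland ancestor,
#'   in `[1, M]` of the dataset the record belongs to.
#' @param status One of `"endemic_clade"` (radiated in situ, >= 2 species),
#'   `"non_endemic_singleton"` (single species, still conspecific with its
#'   mainland ancestor) or `"endemic_singleton"` (single species, diverged
#'   from the mainland ancestor by anagenesis or by cladogenesis followed by
#'   extinction of one daughter lineage).
#' @param colonization_age Stem age of the clade, My.
#' @param branching_ages Numeric vector of branching ages (crown and later
#'   splits), My; sorted internally in decreasing order. Empty for
#'   singletons.
#' @return An object of class `clade_record`.
#' @seealso [island_dataset()], [validate_dataset()]
#' @export
clade_record <- function(name, mainland_species_id, status, colonization_age,
                         branching_ages = numeric(0)) {
  status <- match.arg(status,
                      c("endemic_clade", "non_endemic_singleton", "endemic_singleton"))
  rec <- list(
    name = as.character(name),
    mainland_species_id = as.integer(mainland_species_id),
    status = status,
    colonization_age = as.numeric(colonization_age),
    branching_ages = sort(as.numeric(branching_ages), decreasing = TRUE)
  )
  class(rec) <- "clade_record"
  rec
}

clade_size <- function(rec) 1L + length(rec$branching_ages)

#' An island community dataset
#'
#' The phylogenetic data for one island: island age, mainland species pool
#' size and the collection of colonist clade records.
#'
#' @param island_age Age of the island (time of its emergence), My.
#' @param M Mainland species pool size (positive integer).
#' @param clades A list of [clade_record()] objects (possibly empty).
#' @param validate If `TRUE` (default), warn when [validate_dataset()] finds
#'   violations.
#' @return An object of class `island_dataset`.
#' @examples
#' ds <- island_dataset(30, 1000, list(
#'   clade_record("A", 1, "endemic_clade", 10, c(6, 2)),
#'   clade_record("B", 2, "non_endemic_singleton", 4)
#' ))
#' total_species(ds)
#' @export
island_dataset <- function(island_age, M, clades = list(), validate = TRUE) {
  stopifnot(is.numeric(island_age), length(island_age) == 1L, island_age > 0)
  if (length(clades) && !all(vapply(clades, inherits, logical(1), "clade_record"))) {
    stop("island_dataset: 'clades' must be a list of clade_record objects")
  }
  ds <- list(island_age = as.numeric(island_age), M = as.integer(M),
             clades = unname(clades))
  class(ds) <- "island_dataset"
  if (validate) {
    v <- validate_dataset(ds)
    if (length(v)) warning("island_dataset: ", paste(v, collapse = "; "))
  }
  ds
}

#' @rdname island_dataset
#' @param ds An `island_dataset`.
#' @export
total_species <- function(ds) {
  if (!length(ds$clades)) return(0L)
  sum(vapply(ds$clades, clade_size, integer(1)))
}

#' @export
print.island_dataset <- function(x, ...) {
  cat(sprintf("Island dataset: age %g My, mainland pool %d, %d clade(s), %d species\n",
              x$island_age, x$M, length(x$clades), total_species(x)))
  for (cl in x$clades) {
    cat(sprintf("  %-12s id %-4d %-22s col %8.4f  sizes %d\n",
                cl$name, cl$mainland_species_id, cl$status,
                cl$colonization_age, clade_size(cl)))
  }
  invisible(x)
}

#' Validate an island dataset
#'
#' Checks every type invariant of the data model and returns a character
#' vector of human-readable violations (empty when the dataset is valid).
#' Validation never raises an error.
#'
#' @param ds An [island_dataset()].
#' @return Character vector of violation descriptions; `character(0)` if the
#'   dataset is valid.
#' @details Checked rules: colonization ages are younger than the island age;
#'   every branching age is positive and strictly younger than its clade's
#'   colonization age; branching ages are strictly decreasing; clades with
#'   status `endemic_clade` have at least one branching; singletons have
#'   none; mainland species identifiers lie in `[1, M]` and are distinct
#'   across clades (no recolonization doublets).
#' @export
validate_dataset <- function(ds) {
  out <- character(0)
  say <- function(...) out[[length(out) + 1L]] <<- sprintf(...)
  if (!inherits(ds, "island_dataset")) {
    return("not an island_dataset object")
  }
  if (!is.finite(ds$island_age) || ds$island_age <= 0) {
    say("island_age must be a positive finite number")
  }
  if (is.na(ds$M) || ds$M < 1L) say("mainland pool size M must be >= 1")
  for (cl in ds$clades) {
    nm <- cl$name
    if (!is.finite(cl$colonization_age) || cl$colonization_age <= 0) {
      say("clade %s: colonization age must be positive", nm)
    }
    if (is.finite(ds$island_age) && cl$colonization_age >= ds$island_age) {
      say("clade %s: colonization predates island (%g >= island age %g)",
          nm, cl$colonization_age, ds$island_age)
    }
    if (is.na(cl$mainland_species_id) || cl$mainland_species_id < 1L ||
        cl$mainland_species_id > ds$M) {
      say("clade %s: mainland_species_id outside [1, M]", nm)
    }
    b <- cl$branching_ages
    if (length(b)) {
      if (any(!is.finite(b)) || any(b <= 0)) {
        say("clade %s: branching ages must be positive", nm)
      }
      if (any(b >= cl$colonization_age)) {
        say("clade %s: branching precedes colonization", nm)
      }
      if (length(b) > 1L && any(diff(b) >= 0)) {
        say("clade %s: branching ages must be strictly decreasing", nm)
      }
    }
    if (cl$status == "endemic_clade" && length(b) < 1L) {
      say("clade %s: status endemic_clade requires at least one branching", nm)
    }
    if (cl$status != "endemic_clade" && length(b) > 0L) {
      say("clade %s: singleton status but %d branching age(s)", nm, length(b))
    }
  }
  ids <- vapply(ds$clades, `[[`, integer(1), "mainland_species_id")
  if (anyDuplicated(ids)) {
    say("duplicated mainland_species_id (recolonization doublet): %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out
}

stop_if_invalid <- function(ds) {
  v <- validate_dataset(ds)
  if (length(v)) stop("invalid island dataset: ", paste(v, collapse = "; "),
                      call. = FALSE)
  invisible(ds)
}

#' Event timeline of an island dataset
#'
#' Merges all colonization and branching events across clades into one
#' sequence ordered from the island origin to the present, with the observed
#' (reconstructed) lineage count before and after each event. This is the
#' order in which the likelihood traverses the data.
#'
#' @param ds A valid [island_dataset()].
#' @return A data frame with columns `age`, `event` (`origin`,
#'   `colonization`, `branching`, `present`), `clade` (name, `NA` for
#'   origin/present), `k_before` and `k_after`.
#' @details Ties in age are broken deterministically: colonizations sort
#'   before branchings at the same age, then by clade name, so that repeated
#'   likelihood evaluations traverse an identical sequence.
#' @export
event_timeline <- function(ds) {
  stop_if_invalid(ds)
  rows <- list(data.frame(age = ds$island_age, event = "origin",
                          clade = NA_character_, stringsAsFactors = FALSE))
  for (cl in ds$clades) {
    rows[[length(rows) + 1L]] <- data.frame(
      age = cl$colonization_age, event = "colonization", clade = cl$name,
      stringsAsFactors = FALSE)
    if (length(cl$branching_ages)) {
      rows[[length(rows) + 1L]] <- data.frame(
        age = cl$branching_ages, event = "branching", clade = cl$name,
        stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(age = 0, event = "present",
                                          clade = NA_character_,
                                          stringsAsFactors = FALSE)
  tl <- do.call(rbind, rows)
  evrank <- match(tl$event, c("origin", "colonization", "branching", "present"))
  ord <- order(-tl$age, evrank, tl$clade, method = "radix")
  tl <- tl[ord, , drop = FALSE]
  dk <- ifelse(tl$event %in% c("colonization", "branching"), 1L, 0L)
  tl$k_after <- cumsum(dk)
  tl$k_before <- tl$k_after - dk
  rownames(tl) <- NULL
  tl[, c("age", "event", "clade", "k_before", "k_after")]
}
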