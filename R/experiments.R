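#' Experiments and experiment sets
#'
#' An `experiment` is the unit of coordinate-based meta-analysis: one contrast
#' from one study, contributing a set of activation foci (MNI mm) and a sample
#' size. An `experiment_set` is an ordered collection with unique experiment
#' ids.
#'
#' @param study_id,experiment_id,contrast character scalars.
#' @param n_subjects positive integer; drives the per-experiment kernel width.
#' @param foci numeric n x 3 matrix of MNI coordinates in mm.
#' @param pooling_group optional same-sample marker: experiments sharing a
#'   non-empty `pooling_group` come from (partly) overlapping subject samples
#'   and are merged by [read_experiment_table()] when pooling is on.
#' @export
experiment <- function(study_id, experiment_id, contrast, n_subjects, foci,
                       pooling_group = NA_character_) {
  foci <- rbind_coerce(foci)
  if (nrow(foci) < 1L) stop("experiment must have at least one focus")
  if (!all(is.finite(foci))) stop("foci must be finite")
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) stop("n_subjects must be >= 1")
  structure(list(study_id = as.character(study_id),
                 experiment_id = as.character(experiment_id),
                 contrast = as.character(contrast),
                 n_subjects = n_subjects,
                 foci = unname(foci),
                 pooling_group = pooling_group),
            class = "experiment")
}

#' @rdname experiment
#' @param experiments list of `experiment` objects.
#' @param provenance free-text description of where the corpus came from.
#' @export
experiment_set <- function(experiments, provenance = "") {
  stopifnot(all(vapply(experiments, inherits, TRUE, "experiment")))
  ids <- vapply(experiments, `[[`, "", "experiment_id")
  if (anyDuplicated(ids)) {
    stop("experiment ids must be unique: ", ids[duplicated(ids)][1])
  }
  structure(list(experiments = experiments, provenance = provenance),
            class = "experiment_set")
}

#' @export
length.experiment_set <- function(x) length(x$experiments)

#' @export
print.experiment_set <- function(x, ...) {
  nf <- sum(vapply(x$experiments, function(e) nrow(e$foci), 1L))
  cat(sprintf("<experiment_set: %d experiments, %d foci>\n", length(x), nf))
  invisible(x)
}

#' @rdname experiment
#' @param x an `experiment_set`.
#' @param idx integer or logical index.
#' @return `subset_experiments`: a new `experiment_set`.
#' @export
subset_experiments <- function(x, idx) {
  experiment_set(x$experiments[idx], x$provenance)
}

foci_table_columns <- c("study_id", "experiment_id", "contrast", "n",
                        "x", "y", "z", "pooling_group")

#' Read a foci table
#'
#' Reads the tab-separated foci dialect (header
#' `study_id experiment_id contrast n x y z pooling_group`, one focus per
#' row). With `pooling = "on"`, rows sharing a non-empty `pooling_group` are
#' merged into a single experiment whose foci are concatenated and whose
#' sample size is the *minimum* of the merged rows -- the conservative rule
#' for overlapping samples, since the shared subjects must not be counted
#' twice.
#'
#' @param path TSV file path.
#' @param pooling `"on"` (default) or `"off"`.
#' @return An [experiment_set()].
#' @export
read_experiment_table <- function(path, pooling = c("on", "off")) {
  pooling <- match.arg(pooling)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("empty foci table: ", path)
  missing_cols <- setdiff(setdiff(foci_table_columns, "pooling_group"),
                          names(tab))
  if (length(missing_cols)) {
    stop("foci table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"pooling_group" %in% names(tab)) tab$pooling_group <- ""
  num <- function(col) suppressWarnings(as.numeric(tab[[col]]))
  for (col in c("n", "x", "y", "z")) {
    v <- num(col)
    if (anyNA(v)) {
      stop(sprintf("malformed numeric value in column '%s' at line %d of %s",
                   col, which(is.na(v))[1] + 1L, path))
    }
    tab[[col]] <- v
  }
  as_exp <- function(rows) {
    experiment(rows$study_id[1], rows$experiment_id[1], rows$contrast[1],
               rows$n[1], as.matrix(rows[, c("x", "y", "z")]),
               rows$pooling_group[1])
  }
  exps <- lapply(split(tab, factor(tab$experiment_id,
                                   levels = unique(tab$experiment_id))),
                 as_exp)
  if (pooling == "on") {
    pg <- vapply(exps, `[[`, "", "pooling_group")
    pooled <- !is.na(pg) & nzchar(pg)
    if (any(pooled)) {
      merged <- lapply(split(exps[pooled], pg[pooled]), function(group) {
        experiment(study_id = group[[1]]$study_id,
                   experiment_id = paste0("pooled_",
                                          group[[1]]$pooling_group),
                   contrast = group[[1]]$contrast,
                   n_subjects = min(vapply(group, `[[`, 1L, "n_subjects")),
                   foci = do.call(rbind, lapply(group, `[[`, "foci")),
                   pooling_group = group[[1]]$pooling_group)
      })
      exps <- c(exps[!pooled], merged)
    }
  }
  experiment_set(unname(exps), provenance = path)
}

#' Write a foci table
#'
#' Inverse of [read_experiment_table()]: one row per focus in the standard
#' tab-separated dialect.
#'
#' @param set an [experiment_set()].
#' @param path output TSV path.
#' @export
write_experiment_table <- function(set, path) {
  rows <- lapply(set$experiments, function(e) {
    data.frame(study_id = e$study_id, experiment_id = e$experiment_id,
               contrast = e$contrast, n = e$n_subjects,
               x = e$foci[, 1], y = e$foci[, 2], z = e$foci[, 3],
               pooling_group = ifelse(is.na(e$pooling_group), "",
                                      e$pooling_group))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
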