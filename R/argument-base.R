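#' Guideline knowledge bases
#'
#' A guideline KB holds, for one condition, the set of interventions under
#' discussion: each with a rationale, weighted support and against arguments
#' (verbatim guideline prose), an ordered list of alternative interventions,
#' and an `optional` flag used when no acceptable alternative remains. The
#' KB also names the guideline-recommended plan. All clinical content lives
#' here as data; the dialogue engine itself is domain-agnostic.
#'
#' @param condition symbol, e.g. `"atrial_fibrillation"`.
#' @param interventions named list; each element a list with fields
#'   `rationale` (character), `optional` (logical, default FALSE),
#'   `alternatives` (character vector, default empty), `support` and
#'   `against` (each a list of arguments: lists with `id`, `text` and
#'   optionally `weight`, default 1).
#' @param recommended_plan character vector of intervention names, a subset
#'   of `names(interventions)`.
#' @return An object of class `codel_kb`.
#' @export
guideline_kb <- function(condition, interventions, recommended_plan) {
  stopifnot(is.character(condition), length(condition) == 1L,
            is.list(interventions), length(names(interventions)) > 0L)
  kb <- structure(list(condition = condition,
                       interventions = lapply(interventions, .normalize_iv),
                       recommended_plan = as.character(recommended_plan)),
                  class = "codel_kb")
  validate_kb(kb)
  kb
}

.normalize_iv <- function(iv) {
  norm_args <- function(x, polarity) {
    lapply(x, function(a) {
      if (is.null(a$id) || is.null(a$text)) {
        stop("every argument needs an `id` and a `text`", call. = FALSE)
      }
      list(id = as.character(a$id), polarity = polarity,
           text = as.character(a$text),
           weight = if (is.null(a$weight)) 1 else as.numeric(a$weight))
    })
  }
  list(rationale = as.character(iv$rationale %||% ""),
       optional = isTRUE(iv$optional),
       alternatives = as.character(iv$alternatives %||% character()),
       support = norm_args(iv$support %||% list(), "support"),
       against = norm_args(iv$against %||% list(), "against"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname guideline_kb
#' @param kb a `codel_kb`.
#' @return `validate_kb` returns `kb` invisibly, or stops naming the
#'   offending record (dangling alternative reference, duplicate argument
#'   id, non-positive weight, recommended intervention not defined).
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "codel_kb"))
  defined <- names(kb$interventions)
  missing_rec <- setdiff(kb$recommended_plan, defined)
  if (length(missing_rec)) {
    stop("recommended_plan names undefined interventions: ",
         paste(missing_rec, collapse = ", "), call. = FALSE)
  }
  ids <- character()
  for (nm in defined) {
    iv <- kb$interventions[[nm]]
    dangling <- setdiff(iv$alternatives, defined)
    if (length(dangling)) {
      stop(sprintf("intervention `%s` lists undefined alternative(s): %s",
                   nm, paste(dangling, collapse = ", ")), call. = FALSE)
    }
    for (a in c(iv$support, iv$against)) {
      if (a$weight <= 0) {
        stop(sprintf("argument `%s` of `%s` has non-positive weight",
                     a$id, nm), call. = FALSE)
      }
      ids <- c(ids, a$id)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate argument id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  invisible(kb)
}

#' @export
print.codel_kb <- function(x, ...) {
  cat(sprintf("<codel_kb> condition: %s\n", x$condition))
  cat(sprintf("  recommended plan: %s\n",
              paste(x$recommended_plan, collapse = " + ")))
  for (nm in names(x$interventions)) {
    iv <- x$interventions[[nm]]
    cat(sprintf("  %s%s: %d support / %d against%s\n", nm,
                if (iv$optional) " (optional)" else "",
                length(iv$support), length(iv$against),
                if (length(iv$alternatives))
                  paste0("; alternatives: ",
                         paste(iv$alternatives, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Read / write a guideline KB
#'
#' KB files are YAML with top-level fields `condition`, `recommended_plan`
#' and `interventions` (a map from intervention name to its record). All
#' invariants are validated on load; errors name the offending record.
#'
#' @param path path to a `.yaml` KB file.
#' @return `load_kb` returns a `codel_kb`; `save_kb` returns `path`
#'   invisibly. Saving then loading reproduces the same KB.
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "af_kb.yaml", package = "codel"))
#' kb$recommended_plan
load_kb <- function(path) {
  raw <- yaml::read_yaml(path)
  for (field in c("condition", "recommended_plan", "interventions")) {
    if (is.null(raw[[field]])) {
      stop(sprintf("KB file is missing required field `%s`", field),
           call. = FALSE)
    }
  }
  guideline_kb(raw$condition, raw$interventions,
               unlist(raw$recommended_plan))
}

#' @rdname load_kb
#' @param kb a `codel_kb`.
#' @export
save_kb <- function(kb, path) {
  validate_kb(kb)
  drop_pol <- function(a) a[c("id", "text", "weight")]
  out <- list(
    condition = kb$condition,
    recommended_plan = as.list(kb$recommended_plan),
    interventions = lapply(kb$interventions, function(iv) {
      list(rationale = iv$rationale, optional = iv$optional,
           alternatives = as.list(iv$alternatives),
           support = lapply(iv$support, drop_pol),
           against = lapply(iv$against, drop_pol))
    }))
  yaml::write_yaml(out, path)
  invisible(path)
}

.get_iv <- function(kb, intervention) {
  stopifnot(inherits(kb, "codel_kb"))
  iv <- kb$interventions[[intervention]]
  if (is.null(iv)) {
    stop(sprintf("unknown intervention `%s` in KB for %s",
                 intervention, kb$condition), call. = FALSE)
  }
  iv
}

#' Look up guideline arguments for an intervention
#'
#' @param kb a `codel_kb`.
#' @param intervention intervention name defined in `kb`.
#' @param polarity `"support"` or `"against"`.
#' @return A list of arguments (each with `id`, `polarity`, `text`,
#'   `weight`), in authored order. Errors on an unknown intervention.
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "af_kb.yaml", package = "codel"))
#' sapply(find_arguments(kb, "cardiac_ultrasound", "support"), `[[`, "text")
find_arguments <- function(kb, intervention,
                           polarity = c("support", "against")) {
  polarity <- match.arg(polarity)
  .get_iv(kb, intervention)[[polarity]]
}

#' @rdname find_arguments
#' @return `argument_weight_sum` returns the summed weight of the requested
#'   arguments (0 if none).
#' @export
argument_weight_sum <- function(kb, intervention,
                                polarity = c("support", "against")) {
  args <- find_arguments(kb, intervention, polarity)
  if (!length(args)) 0 else sum(vapply(args, `[[`, numeric(1), "weight"))
}

#' Propose an alternative for a rejected intervention
#'
#' Walks the rejected intervention's authored alternative list and returns
#' the first entry not already rejected in this session, or `NULL` when the
#' alternatives are exhausted (the engine then drops the component if it is
#' optional, or ends without agreement).
#'
#' @param kb a `codel_kb`.
#' @param rejected intervention name defined in `kb`.
#' @param already_rejected character vector of intervention names already
#'   turned down in this session.
#' @return An intervention name, or `NULL`.
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "af_kb.yaml", package = "codel"))
#' propose_alternative(kb, "cardiac_angiography")          # cardiac_ultrasound
#' propose_alternative(kb, "cardiac_angiography",
#'                     already_rejected = "cardiac_ultrasound")  # NULL
propose_alternative <- function(kb, rejected, already_rejected = character()) {
  iv <- .get_iv(kb, rejected)
  remaining <- setdiff(iv$alternatives, already_rejected)
  if (length(remaining)) remaining[[1L]] else NULL
}
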