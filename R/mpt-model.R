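#' Define a multinomial processing tree (MPT) model
#'
#' An MPT model expresses the probability of each observable response
#' category as a sum over tree branches, where every branch is a product of
#' latent-process probabilities \eqn{\theta} or their complements
#' \eqn{1-\theta}. `mpt_model()` builds such a model from a branch table;
#' [cp_model()] builds the canonical cooperation-and-punishment model.
#'
#' @param branches A data frame with columns `tree`, `category`, and `term`,
#'   one row per branch. `term` is the branch product written in EQN syntax,
#'   e.g. `"C*(1-P_moral)*b"`: factors joined by `*`, a complement factor
#'   written `(1-name)`.
#' @param params Optional character vector of parameter names. Defaults to
#'   the parameters appearing in `branches`, in order of first appearance.
#'   Parameters listed here but never used are allowed (and will show up as
#'   non-identified in [check_identifiability()]).
#'
#' @return An object of class `mpt_model`: a list with `branches` (a tibble
#'   with a `factors` list-column), `trees` (named list mapping tree id to
#'   its ordered category labels) and `params`.
#' @seealso [cp_model()], [read_eqn()], [category_probabilities()]
#' @export
#' @examples
#' m <- mpt_model(data.frame(
#'   tree     = "t1",
#'   category = c("hit", "hit", "miss"),
#'   term     = c("d", "(1-d)*g", "(1-d)*(1-g)")
#' ))
#' category_probabilities(m, c(d = 0.5, g = 0.4))
mpt_model <- function(branches, params = NULL) {
  stopifnot(is.data.frame(branches),
            all(c("tree", "category", "term") %in% names(branches)))
  branches <- tibble::as_tibble(branches)
  branches$factors <- lapply(branches$term, parse_branch_term)
  used <- unique(unlist(lapply(branches$factors, function(f) f$param)))
  if (is.null(params)) {
    params <- used
  } else if (!all(used %in% params)) {
    stop("branch term references undefined parameter(s): ",
         paste(setdiff(used, params), collapse = ", "), call. = FALSE)
  }
  trees <- split(branches$category, branches$tree)
  # preserve first-appearance order of trees and of categories within a tree
  tree_ids <- unique(branches$tree)
  trees <- lapply(tree_ids, function(t) unique(branches$category[branches$tree == t]))
  names(trees) <- tree_ids
  structure(
    list(branches = branches, trees = trees, params = params),
    class = "mpt_model"
  )
}

# "C*(1-P_moral)*b" -> tibble(param, complement)
parse_branch_term <- function(term) {
  term <- gsub("[[:space:]]", "", term)
  if (!nzchar(term)) stop("empty branch term", call. = FALSE)
  parts <- strsplit(term, "*", fixed = TRUE)[[1]]
  ok <- grepl("^\\(1-[A-Za-z_][A-Za-z0-9_.]*\\)$|^[A-Za-z_][A-Za-z0-9_.]*$", parts)
  if (!all(ok) || length(parts) == 0L) {
    stop("cannot parse branch term: ", term, call. = FALSE)
  }
  comp <- startsWith(parts, "(")
  param <- ifelse(comp, substr(parts, 4, nchar(parts) - 1L), parts)
  tibble::tibble(param = param, complement = comp)
}

deparse_branch_term <- function(factors) {
  paste(ifelse(factors$complement,
               paste0("(1-", factors$param, ")"),
               factors$param),
        collapse = "*")
}

#' The cooperation-and-punishment MPT model
#'
#' Builds the five-parameter MPT model of cooperation and costly punishment
#' in a simultaneous Prisoner's Dilemma with two partner types. Two trees
#' describe a participant facing a defecting and a cooperating partner; each
#' tree has four categories crossing the participant's choice
#' (cooperate/defect) with the punishment decision (punish/no punish).
#'
#' Parameters:
#' \describe{
#'   \item{`C`}{probability of cooperating, assumed independent of partner
#'     type (both trees share it).}
#'   \item{`P_moral`}{conditional probability of punishing a defecting
#'     partner after the participant cooperated (moral punishment).}
#'   \item{`P_hypocritical`}{conditional probability of punishing a
#'     defecting partner after the participant also defected.}
#'   \item{`P_antisocial`}{conditional probability of punishing a
#'     cooperating partner after the participant defected.}
#'   \item{`b`}{unspecific punishment bias, applied when the
#'     outcome-specific process does not fire; it is the only source of
#'     punishment after mutual cooperation, which identifies it.}
#' }
#'
#' Category order is fixed as (coop_punish, coop_nopunish, defect_punish,
#' defect_nopunish) within each tree, defector-partner tree first.
#'
#' @return An `mpt_model` with 2 trees, 8 categories and 11 branches.
#' @export
#' @examples
#' m <- cp_model()
#' category_probabilities(m, c(C = 0.6, P_moral = 0.5,
#'                             P_hypocritical = 0.3, P_antisocial = 0.1,
#'                             b = 0.2))
cp_model <- function() {
  branches <- tibble::tribble(
    ~tree,                ~category,         ~term,
    "defector_partner",   "coop_punish",     "C*P_moral",
    "defector_partner",   "coop_punish",     "C*(1-P_moral)*b",
    "defector_partner",   "coop_nopunish",   "C*(1-P_moral)*(1-b)",
    "defector_partner",   "defect_punish",   "(1-C)*P_hypocritical",
    "defector_partner",   "defect_punish",   "(1-C)*(1-P_hypocritical)*b",
    "defector_partner",   "defect_nopunish", "(1-C)*(1-P_hypocritical)*(1-b)",
    "cooperator_partner", "coop_punish",     "C*b",
    "cooperator_partner", "coop_nopunish",   "C*(1-b)",
    "cooperator_partner", "defect_punish",   "(1-C)*P_antisocial",
    "cooperator_partner", "defect_punish",   "(1-C)*(1-P_antisocial)*b",
    "cooperator_partner", "defect_nopunish", "(1-C)*(1-P_antisocial)*(1-b)"
  )
  # fix the canonical category order explicitly (tribble order puts
  # defect categories after coop categories already, but be explicit)
  m <- mpt_model(branches,
                 params = c("C", "P_moral", "P_hypocritical",
                            "P_antisocial", "b"))
  ord <- c("coop_punish", "coop_nopunish", "defect_punish", "defect_nopunish")
  m$trees <- list(defector_partner = ord, cooperator_partner = ord)
  m
}

#' Names of the cooperation-and-punishment parameters
#' @return Character vector of the five parameter names in canonical order.
#' @export
cp_param_names <- function() {
  c("C", "P_moral", "P_hypocritical", "P_antisocial", "b")
}

check_params <- function(model, params) {
  params <- unlist(params)
  if (is.null(names(params)) || !all(model$params %in% names(params))) {
    stop("`params` must be a named vector covering: ",
         paste(model$params, collapse = ", "), call. = FALSE)
  }
  p <- params[model$params]
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("all parameters must lie in [0, 1]", call. = FALSE)
  }
  p
}

#' Probability of a single MPT branch
#'
#' A branch probability is the product over its factors of \eqn{\theta}
#' (plain factor) or \eqn{1-\theta} (complement factor).
#'
#' @param factors A branch factor table (`param`, `complement` columns), a
#'   term string such as `"C*(1-P_moral)*b"`, or one row of
#'   `model$branches`.
#' @param params Named numeric vector of parameter values in \[0, 1\].
#' @return A single probability.
#' @export
#' @examples
#' branch_probability("C*(1-P_moral)*b",
#'                    c(C = 0.6, P_moral = 0.5, b = 0.2))  # 0.06
branch_probability <- function(factors, params) {
  if (is.character(factors)) factors <- parse_branch_term(factors)
  if (!all(factors$param %in% names(params))) {
    stop("unknown parameter(s) in branch: ",
         paste(setdiff(factors$param, names(params)), collapse = ", "),
         call. = FALSE)
  }
  th <- unname(params[factors$param])
  prod(ifelse(factors$complement, 1 - th, th))
}

#' Category probabilities of an MPT model
#'
#' Each category's probability is the sum of the probabilities of all
#' branches terminating in it. For every valid parameter vector the
#' probabilities within a tree sum to 1.
#'
#' @param model An [mpt_model()].
#' @param params Named numeric vector of parameter values in \[0, 1\].
#' @param tree Optional tree id to restrict the output to one tree.
#' @return A tibble with columns `tree`, `category`, `prob`, in the model's
#'   canonical tree and category order.
#' @export
category_probabilities <- function(model, params, tree = NULL) {
  stopifnot(inherits(model, "mpt_model"))
  p <- check_params(model, params)
  bp <- vapply(model$branches$factors, branch_probability, numeric(1),
               params = p)
  out <- purrr::map_dfr(names(model$trees), function(t) {
    cats <- model$trees[[t]]
    idx <- model$branches$tree == t
    prob <- vapply(cats, function(cat) {
      sum(bp[idx & model$branches$category == cat])
    }, numeric(1))
    tibble::tibble(tree = t, category = cats, prob = unname(prob))
  })
  tot <- tapply(out$prob, out$tree, sum)
  if (any(abs(tot - 1) > 1e-9)) {
    stop("malformed model: category probabilities of tree(s) ",
         paste(names(tot)[abs(tot - 1) > 1e-9], collapse = ", "),
         " do not sum to 1", call. = FALSE)
  }
  if (!is.null(tree)) out <- out[out$tree == tree, ]
  out
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("<mpt_model> ", length(x$trees), " tree(s), ",
      sum(lengths(x$trees)), " categories, ",
      nrow(x$branches), " branches, parameters: ",
      paste(x$params, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an MPT model from an EQN file
#'
#' The EQN interchange format: the first line gives the number of branch
#' lines; each following line holds a tree label, a category label and the
#' branch product term, whitespace-separated, with complements written
#' `(1-name)` and factors joined by `*`.
#'
#' @param path Path to an EQN file.
#' @return An [mpt_model()].
#' @export
read_eqn <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("EQN file must start with the number of branch lines",
                     call. = FALSE)
  body <- lines[-1]
  if (length(body) < n) stop("EQN file declares ", n, " branches but has ",
                             length(body), call. = FALSE)
  body <- body[seq_len(n)]
  fields <- strsplit(body, "[[:space:]]+")
  bad <- lengths(fields) != 3L
  if (any(bad)) stop("malformed EQN line(s): ",
                     paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  branches <- tibble::tibble(
    tree     = vapply(fields, `[[`, character(1), 1L),
    category = vapply(fields, `[[`, character(1), 2L),
    term     = vapply(fields, `[[`, character(1), 3L)
  )
  mpt_model(branches)
}

#' Write an MPT model to an EQN file
#'
#' Round-trips with [read_eqn()] up to whitespace.
#'
#' @param model An [mpt_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eqn <- function(model, path) {
  stopifnot(inherits(model, "mpt_model"))
  terms <- vapply(model$branches$factors, deparse_branch_term, character(1))
  writeLines(
    c(as.character(nrow(model$branches)),
      paste(model$branches$tree, model$branches$category, terms)),
    path)
  invisible(path)
}
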