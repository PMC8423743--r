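#' Default kernel registry
#'
#' Six bivariate kernels on the normalized unit square, spanning synergy,
#' limiting-factor and antagonism shapes:
#' \describe{
#'   \item{`product`}{`x * y` — synergy; as a self-interaction this is the
#'     quadratic effect `x^2`.}
#'   \item{`min`}{`min(x, y)` — limiting factor (Liebig-type).}
#'   \item{`max`}{`max(x, y)` — either-sufficient.}
#'   \item{`sqmean`}{`((x + y) / 2)^2` — joint-level curvature.}
#'   \item{`absdiff`}{`|x - y|` — antagonism / imbalance; identically zero on
#'     self-pairs, hence not self-admissible.}
#'   \item{`satprod`}{`1 - (1 - x) * (1 - y)` — saturating (noisy-or)
#'     synergy.}
#' }
#' All six are symmetric and bounded on `[0, 1]^2` (each maps into `[0, 1]`).
#' The registry is extensible: see [register_kernel()].
#'
#' @return An object of class `kernel_registry`.
#' @export
default_kernel_registry <- function() {
  reg <- structure(list(), class = "kernel_registry")
  reg <- register_kernel(reg, "product", function(x, y) x * y)
  reg <- register_kernel(reg, "min", function(x, y) pmin(x, y))
  reg <- register_kernel(reg, "max", function(x, y) pmax(x, y))
  reg <- register_kernel(reg, "sqmean", function(x, y) ((x + y) / 2)^2)
  reg <- register_kernel(reg, "absdiff", function(x, y) abs(x - y),
                         self_admissible = FALSE)
  reg <- register_kernel(reg, "satprod", function(x, y) 1 - (1 - x) * (1 - y))
  reg
}

#' Add a kernel to a registry
#'
#' @param registry a `kernel_registry` (possibly empty:
#'   `structure(list(), class = "kernel_registry")`).
#' @param kernel_id unique kernel name.
#' @param fun vectorized binary function on normalized values.
#' @param symmetric logical; `TRUE` when `fun(x, y) == fun(y, x)`.
#' @param self_admissible logical; `FALSE` for kernels degenerate on
#'   self-pairs (e.g. `|x - x| == 0`).
#' @return The extended registry.
#' @export
register_kernel <- function(registry, kernel_id, fun, symmetric = TRUE,
                            self_admissible = TRUE) {
  if (kernel_id %in% kernel_ids(registry))
    stop("kernel_id '", kernel_id, "' already registered")
  registry[[kernel_id]] <- list(id = kernel_id, fun = fun,
                                symmetric = symmetric,
                                self_admissible = self_admissible)
  registry
}

#' Kernel ids of a registry, in registration order
#' @param registry a `kernel_registry`.
#' @return Character vector of kernel ids.
#' @export
kernel_ids <- function(registry) names(registry)

get_kernel <- function(registry, kernel_id) {
  k <- registry[[kernel_id]]
  if (is.null(k)) stop("unregistered kernel_id '", kernel_id, "'")
  k
}

#' Evaluate a registered kernel
#' @param registry a `kernel_registry`.
#' @param kernel_id a registered kernel id.
#' @param x,y normalized values (vectorized).
#' @return Kernel values.
#' @export
eval_kernel <- function(registry, kernel_id, x, y) {
  get_kernel(registry, kernel_id)$fun(x, y)
}

#' An interaction term: a variable pair plus its kernel
#'
#' `var_a == var_b` denotes a self-interaction (with the product kernel, a
#' quadratic effect); each term carries exactly one kernel — the one-hot
#' kernel assignment of the model.
#'
#' @param var_a,var_b catalogue variable names.
#' @param kernel_id registered kernel id.
#' @return An object of class `interaction_term`.
#' @export
interaction_term <- function(var_a, var_b, kernel_id) {
  structure(list(var_a = var_a, var_b = var_b, kernel_id = kernel_id),
            class = "interaction_term")
}

#' @export
print.interaction_term <- function(x, ...) {
  cat(term_key(x), "\n")
  invisible(x)
}

term_key <- function(term) {
  paste(term$var_a, term$var_b, term$kernel_id, sep = ":")
}

validate_terms <- function(terms, catalogue, registry) {
  for (tm in terms) {
    miss <- setdiff(c(tm$var_a, tm$var_b), catalogue$name)
    if (length(miss) > 0L)
      stop("interaction term references missing variable(s): ",
           paste(miss, collapse = ", "))
    k <- get_kernel(registry, tm$kernel_id)
    if (tm$var_a == tm$var_b && !k$self_admissible)
      stop("kernel '", tm$kernel_id, "' is not self-admissible (term on ",
           tm$var_a, ")")
  }
  invisible(terms)
}

#' Materialize the interaction matrix Z
#'
#' Column *m* is the term's kernel evaluated on its two (normalized) variable
#' columns: `Z[i, m] = K_kernel(m)(X[i, var_a], X[i, var_b])`.
#'
#' @param panel a normalized `sample_panel`.
#' @param terms list of [interaction_term()]s.
#' @param registry a `kernel_registry`.
#' @return Numeric matrix `n x length(terms)` with term keys as column names;
#'   a zero-column matrix for an empty term list.
#' @export
build_interaction_matrix <- function(panel, terms,
                                     registry = default_kernel_registry()) {
  if (!panel$normalized)
    stop("panel must be normalized before building interactions")
  validate_terms(terms, panel$catalogue, registry)
  n <- n_samples(panel)
  Z <- matrix(0, n, length(terms))
  for (m in seq_along(terms)) {
    tm <- terms[[m]]
    Z[, m] <- eval_kernel(registry, tm$kernel_id,
                          panel$X[, tm$var_a], panel$X[, tm$var_b])
  }
  colnames(Z) <- vapply(terms, term_key, character(1))
  if (length(terms) > 0L && !all(is.finite(Z)))
    stop("non-finite interaction value produced")
  Z
}

#' Enumerate candidate interaction terms
#'
#' Reports the combinatorial size of the interaction search space and yields
#' candidate terms lazily. Counting follows the ordered-pair convention
#' (`p^2` variable pairs including self-pairs; each pair counts every
#' admissible kernel), while the iterator deduplicates: for symmetric kernels
#' only the canonical ordering `index(var_a) <= index(var_b)` is emitted, so
#' no redundant mirror term is ever searched.
#'
#' @param catalogue a `variable_catalogue`.
#' @param registry a `kernel_registry`.
#' @param allow_self include self-pairs (quadratic effects).
#' @param pair_filter optional function `(category_a, category_b) -> logical`
#'   restricting pairs (e.g. environment-by-management only).
#' @return A list with `n_pairs` (ordered, incl. self when allowed),
#'   `n_terms` (ordered pairs times admissible kernels), `n_search_terms`
#'   (deduplicated terms the iterator will emit), and `next_term()`, a
#'   closure returning the next `interaction_term` or `NULL` when exhausted.
#' @export
enumerate_candidates <- function(catalogue,
                                 registry = default_kernel_registry(),
                                 allow_self = TRUE, pair_filter = NULL) {
  p <- nrow(catalogue)
  vn <- catalogue$name
  vc <- catalogue$category
  kids <- kernel_ids(registry)
  self_ok <- vapply(kids, function(k) registry[[k]]$self_admissible,
                    logical(1))
  sym <- vapply(kids, function(k) registry[[k]]$symmetric, logical(1))
  keep_pair <- function(i, j) {
    is.null(pair_filter) || isTRUE(pair_filter(vc[i], vc[j]))
  }
  ## ordered-pair accounting (the field's reporting convention)
  n_pairs <- 0L
  n_terms <- 0L
  n_search <- 0L
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (!allow_self && i == j) next
    if (!keep_pair(i, j)) next
    n_pairs <- n_pairs + 1L
    adm <- if (i == j) sum(self_ok) else length(kids)
    n_terms <- n_terms + adm
    if (i < j || (i == j)) {
      ## canonical side: count deduplicated search terms
      if (i == j) n_search <- n_search + sum(self_ok)
      else n_search <- n_search + sum(sym) +
          2L * sum(!sym)  # asymmetric kernels keep both orderings
    }
  }
  ## lazy iterator over canonical (deduplicated) terms
  i <- 1L; j <- 0L; klist <- character(0); kpos <- 0L; pending <- NULL
  advance_pair <- function() {
    repeat {
      j <<- j + 1L
      if (j > p) { i <<- i + 1L; j <<- i }
      if (i > p) return(FALSE)
      if (i == j && !allow_self) next
      if (!keep_pair(i, j)) next
      klist <<- if (i == j) kids[self_ok] else kids
      if (length(klist) == 0L) next
      kpos <<- 0L
      return(TRUE)
    }
  }
  next_term <- function() {
    if (!is.null(pending)) { tm <- pending; pending <<- NULL; return(tm) }
    if (kpos >= length(klist) && !advance_pair()) return(NULL)
    kpos <<- kpos + 1L
    kid <- klist[kpos]
    if (i < j && !registry[[kid]]$symmetric)
      pending <<- interaction_term(vn[j], vn[i], kid)
    interaction_term(vn[i], vn[j], kid)
  }
  list(n_pairs = n_pairs, n_terms = n_terms, n_search_terms = n_search,
       next_term = next_term)
}

#' Serialize interaction terms to plain lists (for JSON)
#' @param terms list of `interaction_term`s.
#' @return List of `{var_a, var_b, kernel_id}` lists.
#' @export
terms_to_list <- function(terms) {
  lapply(terms, function(tm)
    list(var_a = tm$var_a, var_b = tm$var_b, kernel_id = tm$kernel_id))
}

#' Rebuild interaction terms from plain lists
#' @param lst list of `{var_a, var_b, kernel_id}` lists.
#' @return List of `interaction_term`s.
#' @export
terms_from_list <- function(lst) {
  lapply(lst, function(e) interaction_term(e$var_a, e$var_b, e$kernel_id))
}
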