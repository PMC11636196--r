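#' Compose year-by-form shares from market shares and form splits
#'
#' Multiplies the year x category market share matrix `E` by the
#' category x form split matrix `F` to obtain the year x form share matrix
#' `G = E F`, i.e. `g_mz = sum_n e_mn f_nz`.  Row-stochasticity is preserved
#' by construction and re-validated on the result.
#'
#' @param E `share_matrix`, years x categories.
#' @param F `share_matrix`, categories x forms; its row labels must equal
#'   `E`'s column labels.
#' @return `share_matrix`, years x forms.
#' @seealso [reallocate_categories()], [allocate_form_production()]
#' @export
compose_form_shares <- function(E, F) {
  validate_share_matrix(E)
  validate_share_matrix(F)
  if (!identical(colnames(E), rownames(F))) {
    mism <- union(setdiff(colnames(E), rownames(F)),
                  setdiff(rownames(F), colnames(E)))
    stop(sprintf(
      "category labels of E and F disagree: %s",
      if (length(mism)) paste(sQuote(mism), collapse = ", ")
      else "same set, different order"
    ), call. = FALSE)
  }
  G <- unclass(E) %*% unclass(F)
  share_matrix(G, row_labels = rownames(E), col_labels = colnames(F))
}

#' Per-form product category allocation
#'
#' For a given material form `z`, rescales the joint share
#' `e_mn * f_nz` by the form's yearly total `g_mz` so that each year's
#' category allocation for that form again sums to one:
#' element `(m, n) = e_mn f_nz / g_mz`.
#'
#' @param E `share_matrix`, years x categories.
#' @param F `share_matrix`, categories x forms.
#' @param form form label or column index into `F`.
#' @param G optional precomputed `compose_form_shares(E, F)`.
#' @return `share_matrix`, years x categories, specific to `form`.
#' @export
reallocate_categories <- function(E, F, form, G = NULL) {
  if (is.null(G)) G <- compose_form_shares(E, F)
  form <- resolve_label(form, colnames(F), "form")
  g <- unclass(G)[, form]
  zero <- which(g <= 0)
  if (length(zero) > 0L) {
    stop(sprintf(
      "form '%s' has zero market share in year(s) %s; no category allocation exists",
      form, paste(rownames(G)[zero], collapse = ", ")
    ), call. = FALSE)
  }
  out <- sweep(unclass(E) * rep(unclass(F)[, form], each = nrow(E)), 1L, g, "/")
  share_matrix(out, row_labels = rownames(E), col_labels = colnames(E))
}

#' Split a total production series into one form
#'
#' Multiplies every Monte-Carlo production sample of year `m` by the form
#' share `g_mz`.  Summed over all forms the outputs reproduce the total
#' series sample-wise.
#'
#' @param P numeric matrix of production masses (metric tonnes/year),
#'   years in rows (rownames = year labels), Monte-Carlo samples in columns.
#'   A numeric vector is treated as a single sample per year.
#' @param G `share_matrix`, years x forms, from [compose_form_shares()].
#' @param form form label or column index into `G`.
#' @return matrix of the same shape as `P` with the form's production.
#' @export
allocate_form_production <- function(P, G, form) {
  P <- as_production_matrix(P, years = rownames(G))
  form <- resolve_label(form, colnames(G), "form")
  missing_years <- setdiff(rownames(P), rownames(G))
  if (length(missing_years) > 0L) {
    stop(sprintf("year(s) %s absent from the form share matrix",
                 paste(missing_years, collapse = ", ")), call. = FALSE)
  }
  if (any(P < 0)) stop("production masses must be non-negative", call. = FALSE)
  out <- P * as.numeric(unclass(G)[rownames(P), form])
  dimnames(out) <- dimnames(P)
  out
}

as_production_matrix <- function(P, years = NULL) {
  if (is.null(dim(P))) {
    P <- matrix(P, ncol = 1L,
                dimnames = list(names(P) %||% years, NULL))
  }
  if (is.null(rownames(P))) {
    stop("production series needs year labels (rownames or names)",
         call. = FALSE)
  }
  P
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_label <- function(lab, labels, what) {
  if (is.numeric(lab)) {
    if (lab < 1 || lab > length(labels)) {
      stop(sprintf("%s index %d out of range", what, lab), call. = FALSE)
    }
    return(labels[lab])
  }
  if (!lab %in% labels) {
    stop(sprintf("unknown %s '%s'; available: %s", what, lab,
                 paste(labels, collapse = ", ")), call. = FALSE)
  }
  lab
}

#' Combine market fractions with a form-by-application distribution
#'
#' Given the overall market fraction of each form (vector `A`, summing to 1)
#' and a form x application distribution matrix `B` (rows summing to 1),
#' derives the form mix within each application: the entry for
#' (application, form) is proportional to `A[form] * B[form, application]`,
#' normalised so each application row sums to one.
#'
#' @param A named numeric vector of form market fractions, summing to 1.
#' @param B numeric matrix, forms x applications, rows summing to 1; its row
#'   names must match `names(A)`.
#' @param tol validation tolerance.
#' @return `share_matrix`, applications x forms.
#' @export
combine_market_matrices <- function(A, B, tol = 1e-9) {
  if (is.null(names(A)) || is.null(rownames(B)) ||
      !identical(sort(names(A)), sort(rownames(B)))) {
    stop("A and B must be labelled over the same set of forms", call. = FALSE)
  }
  if (abs(sum(A) - 1) > tol) stop("form market fractions A must sum to 1", call. = FALSE)
  validate_share_matrix(share_matrix(B, tol = tol), tol = tol)
  B <- B[names(A), , drop = FALSE]
  W <- t(B * A)                      # applications x forms, unnormalised
  tot <- rowSums(W)
  zero <- which(tot <= 0)
  if (length(zero) > 0L) {
    stop(sprintf("application(s) %s receive zero weight from every form",
                 paste(sQuote(rownames(W)[zero]), collapse = ", ")),
         call. = FALSE)
  }
  share_matrix(W / tot, row_labels = colnames(B), col_labels = names(A))
}

#' Build the form split row of one product category
#'
#' Evaluates one of four split rules and returns a row over the material
#' forms that sums to one:
#' \describe{
#'   \item{`explicit`}{`shares` gives the fractions directly (named by form).}
#'   \item{`equal_split`}{fraction `1/k` to each of the `k` forms listed in
#'     `forms_used`, zero elsewhere.}
#'   \item{`go_halving`}{`shares` gives fractions for a material and its
#'     oxide (e.g. pristine graphene and graphene oxide); the oxide share is
#'     halved between the oxide and its reduced form, so `(a, b)` becomes
#'     `(a, b/2, b/2)`.  The reduced form is the third label in `forms`.}
#'   \item{`mixture`}{weighted sum of named base rows: `components` is a
#'     list of rows (each summing to 1 over `forms`) and `weights` their
#'     mixing fractions, which must sum to 1.}
#' }
#'
#' @param spec a list with element `rule` and the rule's parameters as
#'   described above.
#' @param forms ordered character vector of form labels; the default is the
#'   graphene family `c("pG", "GO", "rGO")`.
#' @return named numeric vector over `forms`, summing to 1.
#' @examples
#' apply_split_rules(list(rule = "equal_split",
#'                        forms_used = c("pG", "GO", "rGO")))
#' apply_split_rules(list(rule = "go_halving", shares = c(pG = 0, GO = 1)))
#' @export
apply_split_rules <- function(spec, forms = gbm_forms()) {
  if (!is.list(spec) || is.null(spec$rule)) {
    stop("category spec must be a list with a 'rule' element", call. = FALSE)
  }
  row <- switch(
    spec$rule,
    explicit = {
      out <- numeric(length(forms)); names(out) <- forms
      if (is.null(names(spec$shares)) || !all(names(spec$shares) %in% forms)) {
        stop("explicit shares must be named by known forms", call. = FALSE)
      }
      out[names(spec$shares)] <- spec$shares
      out
    },
    equal_split = {
      used <- spec$forms_used %||% forms
      if (!all(used %in% forms)) {
        stop("equal_split lists forms outside the form vocabulary", call. = FALSE)
      }
      out <- numeric(length(forms)); names(out) <- forms
      out[used] <- 1 / length(used)
      out
    },
    go_halving = {
      if (length(spec$shares) != 2L || length(forms) < 3L) {
        stop("go_halving needs two base shares and at least three forms",
             call. = FALSE)
      }
      a <- unname(spec$shares[1L]); b <- unname(spec$shares[2L])
      out <- numeric(length(forms)); names(out) <- forms
      out[1:3] <- c(a, b / 2, b / 2)
      out
    },
    mixture = {
      w <- spec$weights
      if (abs(sum(w) - 1) > 1e-9) {
        stop("mixture weights must sum to 1", call. = FALSE)
      }
      rows <- lapply(spec$components, function(cmp) {
        if (is.list(cmp)) apply_split_rules(cmp, forms) else cmp[forms]
      })
      Reduce(`+`, Map(`*`, rows, as.list(w)))
    },
    stop(sprintf("unknown split rule '%s'", spec$rule), call. = FALSE)
  )
  if (abs(sum(row) - 1) > 1e-9) {
    stop("split rule produced a row not summing to 1", call. = FALSE)
  }
  names(row) <- forms
  row
}

#' Default form vocabulary for graphene-based materials
#'
#' @return `c("pG", "GO", "rGO")`: pristine graphene, graphene oxide and
#'   reduced graphene oxide, in that order.
#' @export
gbm_forms <- function() c("pG", "GO", "rGO")

#' Default category-by-form split matrix for graphene-based materials
#'
#' The shipped split matrix over the 14 product categories of the European
#' graphene market model.  Values are stored as exact fractions summing to
#' one per row; the percentages usually quoted for these categories are the
#' rounded rendering produced by [format_share_percent()].  Composite-like
#' categories (aerospace/aviation, sporting goods, wind turbines) carry the
#' composite mix, batteries the energy-storage mix, automotive a 90/10
#' composite/other blend, and categories whose form usage is unreported get
#' an equal split across the three forms.  Construction and filtration use
#' only the oxide family, with the oxide share halved between graphene oxide
#' and reduced graphene oxide.
#'
#' @return `share_matrix`, 14 categories x 3 forms.
#' @export
gbm_form_splits <- function() {
  forms <- gbm_forms()
  composite <- c(pG = 0.81, GO = 0.095, rGO = 0.095)
  energy    <- c(pG = 0.57, GO = 0.215, rGO = 0.215)
  rows <- list(
    aerospace_aviation = composite,
    automotive         = c(pG = 0.77, GO = 0.115, rGO = 0.115),
    batteries          = energy,
    sporting_goods     = composite,
    wind_turbines      = composite,
    construction       = apply_split_rules(list(rule = "go_halving",
                                                shares = c(pG = 0, GO = 1))),
    drilling_fluid     = apply_split_rules(list(rule = "equal_split")),
    electronics        = c(pG = 1, GO = 0, rGO = 0),
    filtration         = apply_split_rules(list(rule = "go_halving",
                                                shares = c(pG = 0, GO = 1))),
    medical            = apply_split_rules(list(rule = "equal_split")),
    paints_coatings    = apply_split_rules(list(rule = "equal_split")),
    textiles           = apply_split_rules(list(rule = "equal_split")),
    tire               = apply_split_rules(list(rule = "equal_split")),
    research_development = c(pG = 0.71, GO = 0.17, rGO = 0.12)
  )
  share_matrix(do.call(rbind, rows),
               row_labels = names(rows), col_labels = forms)
}

#' Render share fractions as rounded whole percentages
#'
#' Report-layer formatting: fractions are shown as integer percentages
#' (values below the decimal point rounded), the convention used when the
#' split table is printed.  Note that rounded rows need not sum to 100.
#'
#' @param x numeric vector or matrix of fractions in `[0, 1]`.
#' @return integer percentages with the shape of `x`.
#' @export
format_share_percent <- function(x) {
  out <- round(unclass(x) * 100)
  storage.mode(out) <- "integer"
  out
}

#' Reference 2030 production volumes by form (metric tonnes)
#'
#' Published point estimates of the 2030 European production volume of each
#' graphene form, provided for orientation and external comparison; none of
#' the package computations depend on them.
#'
#' @return named numeric vector (tonnes).
#' @export
gbm_production_2030 <- function() c(pG = 2406, GO = 526, rGO = 527)
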