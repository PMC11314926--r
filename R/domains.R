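#' Labeled source domain
#'
#' Sample collection standing for the labeled source dataset: envelope
#' images with gesture labels, wrist angles, and split tags.
#'
#' @param x `n x channels x width` envelope array.
#' @param gesture Integer gesture labels in 0..5.
#' @param angle Wrist rotation angles in degrees.
#' @param split Character split tags (`train`/`validation`/`test`).
#' @param rotation_amplitude Angle normalization constant (degrees).
#' @return Object of class `labeled_domain`.
#' @export
labeled_domain <- function(x, gesture, angle, split = rep("train", length(gesture)),
                           rotation_amplitude = max(abs(angle), 1)) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == length(gesture),
            length(gesture) == length(angle), length(split) == length(gesture))
  if (!all(gesture %in% 0:5)) stopf("gesture labels must be in 0..5")
  structure(
    list(x = x, gesture = as.integer(gesture), angle = angle, split = split,
         rotation_amplitude = rotation_amplitude),
    class = "labeled_domain"
  )
}

#' Unlabeled target domain with quarantined labels
#'
#' The target domain exposes only the envelope images; the true gesture
#' labels and angles are retained for evaluation but sealed in a private
#' environment that adaptation code never touches. They are only reachable
#' through [quarantined_labels()], which no `adapt_*` routine calls (an
#' audit test enforces this).
#'
#' @inheritParams labeled_domain
#' @return Object of class `unlabeled_domain` with public fields `x` and
#'   `split` only.
#' @export
unlabeled_domain <- function(x, gesture, angle, split = rep("train", dim(x)[1]),
                             rotation_amplitude = max(abs(angle), 1)) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == length(gesture))
  vault <- new.env(parent = emptyenv())
  vault$gesture <- as.integer(gesture)
  vault$angle <- angle
  structure(
    list(x = x, split = split, rotation_amplitude = rotation_amplitude,
         .vault = vault),
    class = "unlabeled_domain"
  )
}

#' Unseal quarantined target labels (evaluation only)
#'
#' @param domain An [unlabeled_domain].
#' @return List with `gesture` and `angle`.
#' @export
quarantined_labels <- function(domain) {
  stopifnot(inherits(domain, "unlabeled_domain"))
  list(gesture = domain$.vault$gesture, angle = domain$.vault$angle)
}

#' Extract a domain from a study session
#'
#' @param study An `amode_study`.
#' @param session Session index 1..3.
#' @param labeled If `TRUE` return a [labeled_domain], else an
#'   [unlabeled_domain] with quarantined labels.
#' @param split Optional split filter (`"train"`, `"validation"`, `"test"`);
#'   `NULL` keeps all frames.
#' @return A domain object.
#' @export
session_domain <- function(study, session, labeled = TRUE, split = NULL) {
  stopifnot(inherits(study, "amode_study"))
  s <- study$sessions[[session]]
  keep <- if (is.null(split)) rep(TRUE, length(s$gesture)) else s$split %in% split
  x <- s$envelope[keep, , , drop = FALSE]
  amp <- study$protocol$rotation_amplitude
  if (labeled) {
    labeled_domain(x, s$gesture[keep], s$angle[keep], s$split[keep],
                   rotation_amplitude = amp)
  } else {
    unlabeled_domain(x, s$gesture[keep], s$angle[keep], s$split[keep],
                     rotation_amplitude = amp)
  }
}
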