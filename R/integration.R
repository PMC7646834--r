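# Integration of the two modality calls into one diagnosis.
#
# Decision table (total over all input combinations):
#   1. either modality irregular            -> "further validation"
#   2. LC-MS/MS class within the MSI call's
#      winner-or-ambiguity set              -> the LC-MS/MS class
#   3. otherwise (clear disagreement)       -> "<LC-MS/MS class>/further validation"
# Conflicts resolve toward the proteomics call, which showed the lower
# cross-validated error of the two tracks.
#
# Irregularity ("with irregularities") is operationalized as:
#   (a) MSI: a near-tie (within the margin) between two classes that are
#       NOT the expected near-neighbors RO and ChRCC — e.g. co-scoring of
#       ccRCC and ChRCC, the pattern of the sarcomatoid case;
#   (b) proteomics: a sample falling outside its predicted class's 95%
#       PCA prediction ellipse on PC1-2.

#' Construct an MSI-side diagnosis call
#'
#' Either from explicit fields or from a [patient_call()] via
#' [as_msi_call()].
#'
#' @param winner winning class.
#' @param ambiguous_with classes indistinguishable from the winner
#'   (margin rule).
#' @param irregular irregularity flag (see [flag_irregular()]).
#' @param patient_id optional identifier.
#' @return object of class `msi_call`.
#' @export
msi_call <- function(winner, ambiguous_with = character(0),
                     irregular = FALSE, patient_id = NULL) {
  structure(list(patient_id = patient_id, winner = winner,
                 ambiguous_with = setdiff(ambiguous_with, winner),
                 irregular = isTRUE(irregular)),
            class = "msi_call")
}

#' Construct an LC-MS/MS-side diagnosis call
#'
#' @param class predicted class.
#' @param irregular irregularity flag (e.g. outside the class's PCA
#'   prediction ellipse).
#' @param patient_id optional identifier.
#' @return object of class `lcms_call`.
#' @export
lcms_call <- function(class, irregular = FALSE, patient_id = NULL) {
  structure(list(patient_id = patient_id, class = class,
                 irregular = isTRUE(irregular)),
            class = "lcms_call")
}

#' Flag an irregular MSI call
#'
#' Rule (a): the call is irregular when some class scores within the
#' margin of the winner AND that pair is not \{RO, ChRCC\} — RO-ChRCC
#' similarity is histologically expected, while co-scoring of other
#' pairs (notably ccRCC with ChRCC) is anomalous and warrants follow-up.
#'
#' @param call a [patient_call()] or [msi_call()] with an ambiguity set.
#' @param exempt_pair unordered class pair treated as expected neighbors
#'   (default RO, ChRCC).
#' @return list with `irregular` (logical) and `reason` (string, empty
#'   when regular).
#' @export
flag_irregular <- function(call, exempt_pair = c("RO", "ChRCC")) {
  winner <- x_winner(call)
  amb <- x_ambiguous(call)
  for (other in amb) {
    if (!setequal(c(winner, other), exempt_pair)) {
      return(list(
        irregular = TRUE,
        reason = sprintf("near-tie between %s and %s is not an expected pair",
                         winner, other)
      ))
    }
  }
  list(irregular = FALSE, reason = "")
}

x_winner <- function(call) {
  if (inherits(call, "patient_call") || inherits(call, "msi_call")) call$winner
  else stopf("expected a patient_call or msi_call")
}

x_ambiguous <- function(call) {
  if (!is.null(call$ambiguous_with)) call$ambiguous_with else character(0)
}

#' Flag a proteomics sample outside its class's prediction ellipse
#'
#' Rule (b): given a [pca_with_ellipses()] result, a sample is irregular
#' when its PC1-2 score lies outside the 95% prediction ellipse of the
#' class it was assigned to.
#'
#' @param pca a [pca_with_ellipses()] result.
#' @param sample_index row index of the sample in the PCA scores.
#' @param assigned_class the class whose ellipse to test against.
#' @return list with `irregular` and `reason`.
#' @export
flag_outside_ellipse <- function(pca, sample_index, assigned_class) {
  ell <- pca$ellipses[[assigned_class]]
  if (is.null(ell)) {
    return(list(irregular = FALSE,
                reason = sprintf("no ellipse available for class %s",
                                 assigned_class)))
  }
  inside <- in_ellipse(pca$scores[sample_index, 1:2], ell)
  if (inside) list(irregular = FALSE, reason = "")
  else list(irregular = TRUE,
            reason = sprintf("outside the %s 95%% prediction ellipse",
                             assigned_class))
}

#' Integrate MSI and LC-MS/MS calls into one diagnosis
#'
#' Applies the decision table in the source header. The conclusion is a
#' class, `"<class>/further validation"` (clear modality disagreement,
#' resolved toward proteomics), or `"further validation"` (irregularity
#' on either side).
#'
#' @param msi an [msi_call()] (or [patient_call()], taken as regular
#'   unless [flag_irregular()] fires).
#' @param lcms an [lcms_call()] or plain class string.
#' @return object of class `integrated_diagnosis`: `patient_id`,
#'   `msi_call`, `lcms_call`, `conclusion`, `rule` (which table row
#'   fired).
#' @export
integrate_calls <- function(msi, lcms) {
  if (missing(msi) || is.null(msi)) stopf("MSI call is missing")
  if (missing(lcms) || is.null(lcms)) stopf("LC-MS/MS call is missing")
  if (inherits(msi, "patient_call")) {
    msi <- msi_call(msi$winner, msi$ambiguous_with,
                    irregular = flag_irregular(msi)$irregular,
                    patient_id = msi$patient_id)
  }
  if (is.character(lcms)) lcms <- lcms_call(lcms)
  if (!inherits(msi, "msi_call") || !inherits(lcms, "lcms_call")) {
    stopf("expected an msi_call and an lcms_call")
  }
  if (msi$irregular || lcms$irregular) {
    conclusion <- "further validation"
    rule <- "irregular"
  } else if (lcms$class %in% c(msi$winner, msi$ambiguous_with)) {
    conclusion <- lcms$class
    rule <- if (lcms$class == msi$winner && length(msi$ambiguous_with) == 0) {
      "concordant"
    } else "ambiguity_resolved"
  } else {
    conclusion <- paste0(lcms$class, "/further validation")
    rule <- "discordant"
  }
  structure(
    list(patient_id = msi$patient_id %||% lcms$patient_id,
         msi_call = msi, lcms_call = lcms,
         conclusion = conclusion, rule = rule),
    class = "integrated_diagnosis"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.integrated_diagnosis <- function(x, ...) {
  cat(sprintf("<integrated_diagnosis>%s %s (%s)\n",
              if (!is.null(x$patient_id)) paste0(" ", x$patient_id) else "",
              x$conclusion, x$rule))
  invisible(x)
}

#' Parse a printed diagnosis string into a call
#'
#' Understands the notation of published integration tables:
#' `"RO"` (plain class), `"RO/ChRCC"` (winner with ambiguity),
#' `"ChRCC with irregularities"` (irregular flag).
#'
#' @param text diagnosis string.
#' @param side `"msi"` or `"lcms"`.
#' @param patient_id optional identifier.
#' @return an [msi_call()] or [lcms_call()].
#' @export
parse_diagnosis <- function(text, side = c("msi", "lcms"), patient_id = NULL) {
  side <- match.arg(side)
  text <- trimws(text)
  irregular <- grepl("with irregularities", text, fixed = TRUE)
  text <- trimws(sub("with irregularities", "", text, fixed = TRUE))
  parts <- trimws(strsplit(text, "/", fixed = TRUE)[[1]])
  if (side == "msi") {
    msi_call(parts[1], ambiguous_with = parts[-1], irregular = irregular,
             patient_id = patient_id)
  } else {
    lcms_call(parts[1], irregular = irregular, patient_id = patient_id)
  }
}

#' Load the published integration table of the 23-patient cohort
#'
#' Reads the package's copy of the printed per-patient diagnosis table
#' (pathologist diagnosis, MSI diagnosis, rapid LC-MS/MS diagnosis,
#' published conclusion). The conclusion column may carry a follow-up
#' pathology annotation after an arrow (sarcomatoid transformation);
#' `expected_conclusion` strips it, keeping the decision itself.
#'
#' @param path TSV path (default: the copy shipped in `extdata`).
#' @return data.frame with columns `pathologist`, `patient`,
#'   `msi_diagnosis`, `lcms_diagnosis`, `conclusion`,
#'   `expected_conclusion`.
#' @export
load_integration_table <- function(path = system.file(
  "extdata", "table1_integration.tsv", package = "histomol")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$expected_conclusion <- trimws(vapply(
    strsplit(df$conclusion, " -> ", fixed = TRUE), `[[`, character(1), 1
  ))
  df
}

#' Apply the integration decision table to a diagnosis table
#'
#' Parses the MSI and LC-MS/MS diagnosis columns of a per-patient table
#' (as loaded by [load_integration_table()]) and integrates each row.
#'
#' @param df data.frame with columns `patient`, `msi_diagnosis`,
#'   `lcms_diagnosis`.
#' @return the input with a `derived_conclusion` column appended.
#' @export
integrate_table <- function(df) {
  df$derived_conclusion <- vapply(seq_len(nrow(df)), function(i) {
    integrate_calls(
      parse_diagnosis(df$msi_diagnosis[i], "msi",
                      patient_id = df$patient[i]),
      parse_diagnosis(df$lcms_diagnosis[i], "lcms",
                      patient_id = df$patient[i])
    )$conclusion
  }, character(1))
  df
}
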