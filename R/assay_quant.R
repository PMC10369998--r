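# Closed-form wet-lab quantifications.  All operations are vectorised
# over replicate rows; a thin batch layer (quant_table / average_duplicates)
# averages technical duplicates before applying the formulas.

assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_input("'%s' must be finite numeric", name)
  }
  invisible(x)
}

#' CRISPR editing (deletion) efficiency from qPCR
#'
#' The intact target allele is amplified in edited and wild-type cells;
#' a copy-number control gene normalises template input.  With
#' `dCt = Ct_target - Ct_control` in each cell population, the fraction
#' of intact alleles remaining in edited cells is `2^-(dCt_edited -
#' dCt_wt)`, giving
#' `efficiency = (1 - 2^-(dCt_edited - dCt_wt)) * 100` percent: one
#' cycle later in edited cells means half the template, i.e. 50%
#' editing.  Values can be negative (edited amplifies better than
#' wild type); they are reported unclamped with a warning.
#'
#' @param ct_target_edited,ct_ref_edited Target and control-gene Ct in
#'   the edited population.
#' @param ct_target_wt,ct_ref_wt The same in wild-type cells.
#' @return Editing efficiency in percent.
#' @examples
#' editing_efficiency(26, 20, 25, 20)  # one cycle later -> 50
#' editing_efficiency(27, 20, 25, 20)  # two cycles later -> 75
#' @export
editing_efficiency <- function(ct_target_edited, ct_ref_edited,
                               ct_target_wt, ct_ref_wt) {
  assert_finite(ct_target_edited, "ct_target_edited")
  assert_finite(ct_ref_edited, "ct_ref_edited")
  assert_finite(ct_target_wt, "ct_target_wt")
  assert_finite(ct_ref_wt, "ct_ref_wt")
  ddct <- (ct_target_edited - ct_ref_edited) - (ct_target_wt - ct_ref_wt)
  eff <- (1 - 2^(-ddct)) * 100
  if (any(eff < 0)) {
    warning("negative editing efficiency (edited amplifies better than WT); reported unclamped")
  }
  eff
}

#' Relative expression by the 2^-ddCt method
#'
#' `fold = 2^-((Ct_target_sample - Ct_ref_sample) - (Ct_target_control -
#' Ct_ref_control))`; the control measured against itself is exactly 1.
#' Shifting all four Ct values by a constant leaves the fold unchanged.
#'
#' @param ct_target_s,ct_ref_s Target and reference-gene Ct in the
#'   sample of interest.
#' @param ct_target_c,ct_ref_c The same in the control condition.
#' @return Fold change relative to control.
#' @examples
#' relative_expression(24, 20, 25, 20)  # target one cycle earlier -> 2
#' @export
relative_expression <- function(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c) {
  assert_finite(ct_target_s, "ct_target_s")
  assert_finite(ct_ref_s, "ct_ref_s")
  assert_finite(ct_target_c, "ct_target_c")
  assert_finite(ct_ref_c, "ct_ref_c")
  2^(-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c)))
}

#' Insulin secretion as percent of content, and fold over basal
#'
#' Secreted insulin is normalised as a percentage of total cellular
#' insulin content; stimulation is expressed as the ratio of stimulated
#' to basal (low-glucose) percentages.
#'
#' @param secreted Secreted insulin (assay units, >= 0).
#' @param content Total insulin content (same units, > 0).
#' @return `secretion_percent()`: percent of content.
#' @examples
#' secretion_percent(1, 100)   # 1
#' fold_over_basal(3, 1)       # 3
#' @export
secretion_percent <- function(secreted, content) {
  assert_finite(secreted, "secreted")
  assert_finite(content, "content")
  if (any(content <= 0)) stop_input("insulin content must be > 0")
  if (any(secreted < 0)) stop_input("secreted insulin must be >= 0")
  100 * secreted / content
}

#' @rdname secretion_percent
#' @param stim_percent,basal_percent Secretion percentages under
#'   stimulation and at basal glucose (> 0).
#' @return `fold_over_basal()`: stimulated / basal ratio.
#' @export
fold_over_basal <- function(stim_percent, basal_percent) {
  assert_finite(stim_percent, "stim_percent")
  assert_finite(basal_percent, "basal_percent")
  if (any(basal_percent <= 0)) stop_input("basal secretion must be > 0")
  stim_percent / basal_percent
}

#' Dual-luciferase relative activity
#'
#' Firefly luminescence is normalised to the co-transfected Renilla
#' internal control, then expressed relative to the empty-vector
#' control: `(firefly/renilla) / (firefly_ctrl/renilla_ctrl)`.
#'
#' @param firefly,renilla Test-construct luminescence pair.
#' @param firefly_ctrl,renilla_ctrl Control-construct pair.
#' @return Relative luciferase activity (control vs itself = 1).
#' @export
luciferase_activity <- function(firefly, renilla, firefly_ctrl, renilla_ctrl) {
  assert_finite(firefly, "firefly")
  assert_finite(renilla, "renilla")
  assert_finite(firefly_ctrl, "firefly_ctrl")
  assert_finite(renilla_ctrl, "renilla_ctrl")
  if (any(renilla <= 0) || any(renilla_ctrl <= 0) || any(firefly_ctrl <= 0)) {
    stop_input("renilla readings and control firefly must be > 0")
  }
  (firefly / renilla) / (firefly_ctrl / renilla_ctrl)
}

#' Growth-curve normalisation to day 0
#'
#' Divides an optical-density series by its day-0 value; the day-0
#' entry becomes exactly 1.
#'
#' @param od_series Numeric OD values over the time course.
#' @param od_day0 OD at day 0 (> 0).
#' @return Normalised series.
#' @examples
#' growth_normalize(c(0.2, 0.4, 0.8), 0.2)
#' @export
growth_normalize <- function(od_series, od_day0) {
  assert_finite(od_series, "od_series")
  assert_finite(od_day0, "od_day0")
  if (length(od_day0) != 1L || od_day0 <= 0) {
    stop_input("od_day0 must be a single value > 0")
  }
  od_series / od_day0
}

#' Average technical duplicates
#'
#' Collapses replicate rows (e.g. qPCR duplicates) by the mean of every
#' numeric column within groups defined by the key columns.
#'
#' @param df Input `data.frame`.
#' @param key_cols Character vector of grouping columns.
#' @return One row per key combination.
#' @export
average_duplicates <- function(df, key_cols) {
  missing <- setdiff(key_cols, names(df))
  if (length(missing) > 0L) stop_input("missing key column '%s'", missing[1L])
  num_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1L))], key_cols)
  out <- aggregate(df[num_cols], by = df[key_cols], FUN = mean)
  out[do.call(order, out[key_cols]), , drop = FALSE]
}

#' Apply an assay quantification to a table
#'
#' Batch layer behind the command-line `quant` subcommand.  Expected
#' input columns: `efficiency` — `ct_target_edited`, `ct_ref_edited`,
#' `ct_target_wt`, `ct_ref_wt`; `expression` — `ct_target_sample`,
#' `ct_ref_sample`, `ct_target_control`, `ct_ref_control`; `gsis` —
#' `secreted`, `content` and optionally `condition` (rows with
#' `condition == "basal"` define, per `sample_id`, the basal level for
#' the fold column); `luciferase` — `firefly`, `renilla`,
#' `firefly_ctrl`, `renilla_ctrl`; `growth` — `day`, `od`, grouped by
#' `sample_id` when present.
#'
#' @param kind One of `"efficiency"`, `"expression"`, `"gsis"`,
#'   `"luciferase"`, `"growth"`.
#' @param df Input table.
#' @return `df` with the derived column(s) appended.
#' @export
quant_table <- function(kind = c("efficiency", "expression", "gsis",
                                 "luciferase", "growth"), df) {
  kind <- match.arg(kind)
  need <- function(cols) {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0L) {
      stop_input("'%s' table is missing column '%s'", kind, missing[1L])
    }
  }
  switch(kind,
    efficiency = {
      need(c("ct_target_edited", "ct_ref_edited", "ct_target_wt", "ct_ref_wt"))
      df$efficiency_percent <- editing_efficiency(
        df$ct_target_edited, df$ct_ref_edited, df$ct_target_wt, df$ct_ref_wt)
      df
    },
    expression = {
      need(c("ct_target_sample", "ct_ref_sample",
             "ct_target_control", "ct_ref_control"))
      df$fold <- relative_expression(df$ct_target_sample, df$ct_ref_sample,
                                     df$ct_target_control, df$ct_ref_control)
      df
    },
    gsis = {
      need(c("secreted", "content"))
      df$percent <- secretion_percent(df$secreted, df$content)
      if (!is.null(df$condition)) {
        grp <- if (is.null(df$sample_id)) rep("all", nrow(df)) else df$sample_id
        basal <- tapply(df$percent[df$condition == "basal"],
                        grp[df$condition == "basal"], mean)
        df$fold_over_basal <- df$percent / as.numeric(basal[grp])
      }
      df
    },
    luciferase = {
      need(c("firefly", "renilla", "firefly_ctrl", "renilla_ctrl"))
      df$relative_activity <- luciferase_activity(
        df$firefly, df$renilla, df$firefly_ctrl, df$renilla_ctrl)
      df
    },
    growth = {
      need(c("day", "od"))
      grp <- if (is.null(df$sample_id)) rep("all", nrow(df)) else df$sample_id
      df$normalized <- NA_real_
      for (g in unique(grp)) {
        idx <- grp == g
        day0 <- df$od[idx & df$day == 0]
        if (length(day0) != 1L) {
          stop_input("growth series '%s' needs exactly one day-0 row", g)
        }
        df$normalized[idx] <- growth_normalize(df$od[idx], day0)
      }
      df
    })
}
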