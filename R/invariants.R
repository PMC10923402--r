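# Exhaustive structural-constraint audit of a generated population. Used by
# the test suite and the acceptance script: a valid population yields zero
# violation rows.

#' Audit a population against the structural constraints
#'
#' Checks every household and individual: member count equals household
#' size; one-person households (and only those) are Single; roles follow
#' position (head, spouse in couples/families, children afterwards); the
#' spouse's gender is opposite to the head's; integer ages lie inside
#' their age class; persons under 18 are students with inactive SPC (8);
#' persons 65 or over are employed or retired, and retirees carry SPC 7;
#' heads respect the minimum age (21 in multi-person households, 18 for
#' singles); the mother (female head or spouse) is at least the configured
#' gap older than every child.
#'
#' @param population A `synth_population`.
#' @param constraints See [default_constraints()].
#' @return Data frame of violations (`hid`, `rule`); zero rows when the
#'   population is valid.
#' @export
check_population <- function(population,
                             constraints = default_constraints()) {
  ind <- population$individuals
  hh <- population$households
  bad <- list()
  note <- function(hids, rule) {
    if (length(hids)) {
      bad[[length(bad) + 1L]] <<- data.frame(hid = unique(hids),
                                             rule = rule,
                                             stringsAsFactors = FALSE)
    }
  }

  sizes <- table(factor(ind$hid, levels = hh$hid))
  note(hh$hid[as.integer(sizes) != hh$hh_size], "member count != size")
  note(hh$hid[(hh$hh_size == 1L) != (hh$hh_type == "Single")],
       "size-1 / Single mismatch")

  expected_role <- role_for_position(ind$hh_type, ind$pos)
  note(ind$hid[ind$role != expected_role], "role by position")

  heads <- ind[ind$pos == 1L, ]
  spouses <- ind[ind$role == "spouse", ]
  hg <- heads$gender[match(spouses$hid, heads$hid)]
  note(spouses$hid[spouses$gender == hg], "spouse gender complement")

  ci <- match(ind$age_class, AGE_CLASSES)
  note(ind$hid[is.na(ci) | ind$age < AGE_LO[ci] | ind$age > AGE_HI[ci]],
       "age outside class")

  minors <- ind$age < constraints$adult_age
  note(ind$hid[minors & (ind$activity != "student" |
                           ind$spc != SPC_INACTIVE)],
       "under-18 schoolchild rule")

  old <- ind$age >= constraints$retire_age
  note(ind$hid[old & !ind$activity %in% c("Employed", "retired")],
       "65+ retired default")
  note(ind$hid[ind$activity == "retired" & ind$spc != SPC_RETIRED],
       "retired SPC")
  note(ind$hid[ind$activity == "student" & ind$spc != SPC_INACTIVE],
       "student SPC")

  head_min <- ifelse(heads$hh_size > 1L, constraints$head_min_age_multi,
                     constraints$head_min_age_single)
  note(heads$hid[heads$age < head_min], "head minimum age")

  mothers <- ind[ind$role %in% c("head", "spouse") &
                   ind$gender == "Female", ]
  children <- ind[ind$role == "child", ]
  m_age <- mothers$age[match(children$hid, mothers$hid)]
  gap_bad <- !is.na(m_age) &
    (m_age - children$age) < constraints$mother_child_gap
  note(children$hid[gap_bad], "mother-child age gap")

  out <- if (length(bad)) do.call(rbind, bad) else
    data.frame(hid = integer(0), rule = character(0))
  rownames(out) <- NULL
  out
}
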