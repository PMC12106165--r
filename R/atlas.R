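#  The morphological atlas: a declarative rule engine relating anatomical
#  regions and pathological changes to disease labels.  Rules are data
#  (YAML), not code, so new diseases are added by adding a rule.

.rules_cache <- new.env(parent = emptyenv())

validate_rules <- function(rules) {
  adm <- admissibility_table()
  for (r in rules) {
    if (is.null(r$disease) || !nzchar(r$disease)) abort("atlas rule without a disease label")
    if ((is.null(r$requires) || !length(r$requires)) && (is.null(r$where) || !length(r$where)))
      abort("atlas rule '", r$disease, "': needs required changes or a parameter predicate")
    for (q in r$requires) {
      if (!q$change %in% change_labels())
        abort("atlas rule '", r$disease, "': unknown change '", q$change, "'")
      if (!identical(q$region, "any") &&
          !any(adm$region == q$region & adm$change == q$change))
        abort("atlas rule '", r$disease, "': inadmissible pair (",
              q$region, ", ", q$change, ")")
    }
    for (w in r$where)
      if (!w$op %in% c("lt", "le", "gt", "ge"))
        abort("atlas rule '", r$disease, "': unknown predicate op '", w$op, "'")
  }
  invisible(rules)
}

#' Read atlas rules from a YAML file
#'
#' @param path rule file (schema: top-level `version` and `rules`, each rule
#'   with `disease`, `priority`, `requires` list of `{region, change}` and
#'   optional `where` list of `{param, op, value}` with op in
#'   lt/le/gt/ge).
#' @return validated list of rules.
#' @export
read_rules <- function(path) {
  doc <- yaml::read_yaml(path)
  validate_rules(doc$rules)
}

#' Write atlas rules to a YAML file
#'
#' @param rules list of rules as returned by [default_rules()] or [read_rules()].
#' @param path output path.
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(list(version = 1L, rules = rules), path)
  invisible(path)
}

#' Default morphological-atlas rules
#'
#' The shipped rule set maps each pathological change to its disease label
#' (ptosis to blepharoptosis; either lid retraction to thyroid-associated
#' ophthalmopathy; the combined entropion/trichiasis change, ectropion and
#' tumour to their diseases; the epicanthus changes to change-level outcome
#' labels) plus one composite rule: BPES requires ptosis, epicanthus
#' inversus, and a short horizontal fissure, and subsumes its components.
#'
#' @return validated list of rules (read from the packaged YAML).
#' @export
default_rules <- function() {
  if (is.null(.rules_cache$default))
    .rules_cache$default <- read_rules(system.file("extdata", "atlas_rules.yaml",
                                                   package = "lidmorph"))
  .rules_cache$default
}

rule_priority <- function(r) if (is.null(r$priority)) 1L else r$priority

predicate_holds <- function(w, report) {
  v <- report[[w$param]]
  if (is.null(v) || is.na(v)) return(FALSE)
  switch(w$op, lt = v < w$value, le = v <= w$value,
         gt = v > w$value, ge = v >= w$value)
}

#' Compose a diagnosis from findings through the atlas
#'
#' Every rule whose required (region, change) pairs all match unconsumed
#' findings and whose parameter predicates hold fires, in descending rule
#' priority; a fired rule consumes the findings it matched, so a
#' higher-priority composite rule (BPES) subsumes its component rules
#' instead of co-reporting them (the subsumption is logged on the
#' diagnosis).  Multimorbidity label sets emerge as the union of fired
#' rules, with no enumeration of combinations.
#'
#' @param findings findings data.frame from one eye.
#' @param report the eye's `morphometry_report` (parameter predicates).
#' @param rules atlas rules, default [default_rules()].
#' @param eye_id identifier carried into the diagnosis.
#' @return object of class `eyelid_diagnosis`: `eye_id`, `diseases` (sorted
#'   character vector, empty = normal), `support` (per-disease evidence),
#'   `subsumed` (log of suppressed component labels), `scores` (per-disease
#'   max supporting finding score).
#' @export
apply_atlas <- function(findings, report, rules = default_rules(), eye_id = "eye1") {
  if (is.null(findings)) findings <- empty_findings()
  unknown <- setdiff(unique(findings$change), change_labels())
  if (length(unknown))
    abort("apply_atlas: unknown change label(s): ", paste(unknown, collapse = ", "),
          " (extend the atlas by adding a rule for them)")
  # canonical order: results must not depend on the order findings arrive in
  if (nrow(findings))
    findings <- findings[order(findings$region, findings$change, -findings$score), ,
                         drop = FALSE]
  consumed <- rep(FALSE, nrow(findings))
  ord <- order(-vapply(rules, rule_priority, 0),
               vapply(rules, function(r) r$disease, ""))
  diseases <- character(); support <- list(); scores <- numeric(); subsumed <- character()
  for (r in rules[ord]) {
    hit <- integer()
    ok <- TRUE
    for (q in r$requires) {
      cand <- which(!consumed & findings$change == q$change &
                    (identical(q$region, "any") | findings$region == q$region))
      cand <- setdiff(cand, hit)
      if (!length(cand)) { ok <- FALSE; break }
      hit <- c(hit, cand[1])
    }
    if (!ok) next
    for (w in r$where) if (!predicate_holds(w, report)) { ok <- FALSE; break }
    if (!ok) next
    if (length(hit)) consumed[hit] <- TRUE
    ev <- findings[hit, , drop = FALSE]
    if (!is.null(r$where) && length(r$where))
      ev <- rbind(ev, data.frame(region = "parameter", change = "predicate",
                                 score = 1,
                                 evidence = paste(vapply(r$where, function(w)
                                   sprintf("%s %s %.2f (observed %.2f)", w$param, w$op,
                                           w$value, report[[w$param]]), ""),
                                   collapse = "; ")))
    if (r$disease %in% diseases) {
      support[[r$disease]] <- rbind(support[[r$disease]], ev)
      scores[r$disease] <- max(scores[r$disease], max(ev$score))
    } else {
      diseases <- c(diseases, r$disease)
      support[[r$disease]] <- ev
      scores[r$disease] <- if (nrow(ev)) max(ev$score) else 1
    }
    if (rule_priority(r) > 1 && length(hit))
      subsumed <- c(subsumed, sprintf("'%s' consumed findings: %s", r$disease,
                                      paste(unique(findings$change[hit]), collapse = ", ")))
  }
  structure(list(eye_id = eye_id, diseases = sort(diseases), support = support,
                 scores = scores, subsumed = subsumed, findings = findings,
                 report = report),
            class = "eyelid_diagnosis")
}

#' @export
print.eyelid_diagnosis <- function(x, ...) {
  cat(sprintf("<eyelid_diagnosis> %s: %s\n", x$eye_id,
              if (length(x$diseases)) paste(x$diseases, collapse = " + ") else "normal"))
  for (d in x$diseases)
    cat(sprintf("  %-35s %s\n", d, paste(x$support[[d]]$evidence, collapse = " | ")))
  if (length(x$subsumed)) cat("  subsumption:", paste(x$subsumed, collapse = "; "), "\n")
  invisible(x)
}
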