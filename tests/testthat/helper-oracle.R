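# Independent oracles used across the suite.

# Brute-force candidate enumeration: repeatedly applies single reaction
# steps (depth-first), independent of the multiset-grid code path in the
# package. Respects caps, pairwise exclusivity and the effective step
# count (hydrolysis multiplicity 1-2 counts once).
bruteForceCandidates <- function(parentFormula, library, maxSteps) {
  seen <- new.env(parent = emptyenv())
  addState <- function(comp, multiset) {
    key <- paste(formatFormula(comp), reactionLabel(multiset))
    if (!is.null(seen[[key]])) return(FALSE)
    seen[[key]] <- list(formula = formatFormula(comp), multiset = multiset)
    TRUE
  }
  excluded <- function(multiset, step) {
    ex <- library$exclusive[match(step, library$name)]
    !is.na(ex) && ex %in% names(multiset)
  }
  recurse <- function(comp, multiset) {
    if (!addState(comp, multiset)) return(invisible(NULL))
    for (i in seq_len(nrow(library))) {
      st <- library$name[i]
      cur <- if (st %in% names(multiset)) multiset[[st]] else 0L
      if (cur + 1L > library$cap[i]) next
      if (excluded(multiset, st)) next
      m2 <- multiset
      m2[st] <- cur + 1L
      m2 <- m2[order(names(m2))]
      if (reactionStepCount(m2) > maxSteps) next
      comp2 <- tryCatch(composeFormula(comp, library$delta[[i]]),
                        error = function(e) NULL)
      if (is.null(comp2)) next
      recurse(comp2, m2)
    }
    invisible(NULL)
  }
  empty <- structure(integer(0), names = character(0))
  recurse(parseFormula(parentFormula), empty)
  states <- as.list(seen)
  unname(sort(vapply(states, function(s) {
    paste(s$formula, reactionLabel(s$multiset))
  }, character(1))))
}

# Wide-open constraints so enumeration tests exercise reachability, not
# the element-range filter.
openConstraints <- function() {
  formulaConstraints(C = c(0, 99), H = c(0, 199), O = c(0, 99),
                     S = c(0, 9), N = c(0, 9), rdb = c(-10, 99))
}

# Printed-label comparison used by coverage checks: multisets match up
# to the hydrolysis (glucose-loss) multiplicity.
matchesUpToHydrolysis <- function(m, printed) {
  a <- m[setdiff(names(m), "hydrolysis")]
  a <- a[order(names(a))]
  b <- printed[setdiff(names(printed), "hydrolysis")]
  b <- b[order(names(b))]
  identical(a, b) &&
    (("hydrolysis" %in% names(m)) == ("hydrolysis" %in% names(printed)))
}
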