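# Independent brute-force reference for code assignment: enumerates every
# feasible line-item multiset under the published time/frequency constraints,
# computes credited minutes by filling the base code to its maximum before
# add-ons, and selects by maximum billable minutes with CoCM-over-BHI
# preference. Deliberately structured as enumeration + selection, unlike the
# engine's sequential precedence logic.

oracle_assign <- function(total, cocm_met, bhi_met, is_fqhc,
                          initial_billed = FALSE, g0512_billed = FALSE,
                          avail = NULL) {
  if (is.null(avail)) {
    avail <- stats::setNames(rep(TRUE, 7),
                             c("99484", "99492", "99493", "99494", "G2214",
                               "G0511", "G0512"))
  }
  candidates <- list()
  add <- function(codes, credited, pref) {
    candidates[[length(candidates) + 1]] <<-
      list(codes = codes, credited = credited, pref = pref)
  }
  add(character(0), numeric(0), 0)

  if (!is_fqhc) {
    if (bhi_met && avail[["99484"]] && total >= 20) {
      add("99484", 20, 1)
    }
    if (cocm_met && avail[["G2214"]] && total >= 16) {
      add("G2214", min(total, 30), 2)
    }
    base <- if (initial_billed) "99493" else "99492"
    bmax <- if (initial_billed) 60 else 70
    bmin <- floor(bmax / 2) + 1
    if (cocm_met && avail[[base]] && total >= bmin) {
      add(base, min(total, bmax), 3)
      if (avail[["99494"]]) {
        for (k in 1:2) {
          codes <- c(base, rep("99494", k))
          credited <- bmax
          residual <- total - bmax
          ok <- TRUE
          for (j in seq_len(k)) {
            cred_j <- min(residual, 30)
            if (cred_j < 16) {
              ok <- FALSE
              break
            }
            credited <- c(credited, cred_j)
            residual <- residual - cred_j
          }
          if (ok) add(codes, credited, 3)
        }
      }
    }
  } else {
    if (bhi_met && avail[["G0511"]] && total >= 20) {
      add("G0511", 20, 1)
    }
    amount <- if (g0512_billed) 60 else 70
    if (cocm_met && avail[["G0512"]] && total >= amount) {
      add("G0512", amount, 3)
    }
  }

  scores <- vapply(candidates,
                   function(c) sum(c$credited) * 10 + c$pref, numeric(1))
  best <- candidates[[which.max(scores)]]
  list(codes = best$codes, credited = best$credited,
       billable = sum(best$credited))
}

# Thread the oracle across a patient's months, mirroring the cross-month
# state rules (99492 / first-G0512 consumption).
oracle_patient <- function(totals, cocm, bhi, is_fqhc, avail = NULL) {
  initial <- FALSE
  g0512 <- FALSE
  lapply(seq_along(totals), function(i) {
    res <- oracle_assign(totals[i], cocm[i], bhi[i], is_fqhc,
                         initial_billed = initial, g0512_billed = g0512,
                         avail = avail)
    if ("99492" %in% res$codes) initial <<- TRUE
    if ("G0512" %in% res$codes) g0512 <<- TRUE
    res
  })
}
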