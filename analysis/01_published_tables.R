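#!/usr/bin/env Rscript
# Reanalysis of the published summary table: headline prevalences, the
# univariate odds-ratio screen with Woolf intervals, and the candidate set
# for the multivariate model. Everything here is integer arithmetic on
# printed counts. Writes results/univariate_screen.csv.

library(pwidnet)
dir.create("results", showWarnings = FALSE)

rep <- yunnan_reported()
cat(sprintf("Participants with complete questionnaires: %d of %d PWID recruited\n",
            rep$n_complete, rep$n_pwid))
cat(sprintf("Needle sharing: %d/%d = %.1f%%\n",
            rep$n_sng, rep$n_complete, 100 * rep$n_sng / rep$n_complete))
cat(sprintf("HIV seropositive: %d/%d = %.1f%%\n",
            rep$n_hiv_positive, rep$n_complete,
            100 * rep$n_hiv_positive / rep$n_complete))
cat(sprintf("Shared with a known HIV-positive partner: %d/%d = %.1f%%\n\n",
            rep$n_shared_with_known_hiv_positive, rep$n_sng,
            100 * rep$n_shared_with_known_hiv_positive / rep$n_sng))

screen <- lapply(yunnan_contingency_tables(), univariate_factor_test)
tab <- do.call(rbind, screen)
rownames(tab) <- NULL
write.csv(tab, "results/univariate_screen.csv", row.names = FALSE)

cand <- select_candidates(screen, alpha = 0.05)
cat("Factors passing the univariate screen (p < 0.05):", length(cand), "\n")
cat(paste(" -", cand, collapse = "\n"), "\n\n")

hiv <- screen[["HIV serostatus"]]
cat(sprintf("HIV seropositive univariate OR: %.1f (%.1f-%.1f)\n",
            hiv$odds_ratio[2], hiv$ci_low[2], hiv$ci_high[2]))
cat("Wrote results/univariate_screen.csv\n")
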