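#!/usr/bin/env Rscript
# Step 3 - statistical reporting over the stored volume table: mean +- SD
# per condition, paired angle contrasts with the */** convention, and the
# per-cell one-way ANOVA across each approach group's three angles.
#
# Reads results/volumes.csv written by step 2 (no re-simulation).

suppressMessages(library(lumbosim))

volumes <- read.csv("results/volumes.csv")
summary_tab <- summarize_volumes(volumes)
contrasts <- angle_contrasts(volumes)

anovas <- do.call(rbind, lapply(split(volumes,
                                      interaction(volumes$group,
                                                  volumes$diameter_mm,
                                                  volumes$attempts)),
  function(cell) {
    gs <- split(cell$removed_volume, cell$angle_deg)
    if (length(gs) < 3) return(NULL)
    a <- anova_volumes(gs)
    data.frame(group = cell$group[1], diameter_mm = cell$diameter_mm[1],
               attempts = cell$attempts[1], F = a$statistic,
               p = a$p_value, flag = a$flag)
  }))
rownames(anovas) <- NULL

write.csv(contrasts, "results/volume_contrasts.csv", row.names = FALSE)
write.csv(anovas, "results/volume_anova.csv", row.names = FALSE)
cat("angle contrasts:\n"); print(contrasts, digits = 3)
cat("\nper-cell ANOVA across angles:\n"); print(anovas, digits = 3)
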