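#!/usr/bin/env Rscript
# Methane-to-electricity economics: normalize each study's yield to a
# 100-day reference period, convert to electrical energy via a
# combined-cycle gas turbine at 60% efficiency, and price it at the feed-in
# tariff of 0.75 CNY/kWh. The two literature scenarios are xylan BMP yields
# reported at 50-day digestion times.

library(bmpkit)

pre <- preprocess_bmp(read_gas_log("results/gas_logs.tsv"),
                      read_channel_meta("results/channel_meta.tsv"))
emp_best <- max(vapply(pre$group_curves, function(cv) cv$cumulative[nrow(cv)],
                       numeric(1)))

scenarios <- data.frame(
  label = c("Li et al.", "Ma et al.", "this work (synthetic)"),
  emp = c(202.90, 133.90, emp_best),
  digestion_time = c(50, 50, 25)
)
tab <- economics_table(scenarios)
write.table(format(tab, digits = 6), "results/economics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

print(tab, digits = 4, row.names = FALSE)
own <- tab[3, ]
for (i in 1:2) {
  cat(sprintf("benefit increase over %s: %.2f%%\n", tab$label[i],
              benefit_increase_pct(own, tab[i, ])))
}
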