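species_id,trait,mean,se
Amobia_signata,H_width,2297.6,109.0
Amobia_signata,E_area,887826.7,93027.5
Amobia_signata,OM_area,341.2,21.9
Amobia_signata,OM_number,2585.2,167.9
Amobia_signata,delta_gamma,3.06,0.10
Amobia_signata,OC_diameter,55.7,3.0
Apodacra_seriemaculata,H_width,1494.0,68.4
Apodacra_seriemaculata,E_area,395699.1,27351.6
Apodacra_seriemaculata,OM_area,273.7,14.0
Apodacra_seriemaculata,OM_number,1447.9,72.6
Apodacra_seriemaculata,delta_gamma,4.08,0.11
Apodacra_seriemaculata,OC_diameter,54.0,3.4
Craticulina_tabaniformis,H_width,2394.1,76.5
Craticulina_tabaniformis,E_area,615394.8,28390.5
Craticulina_tabaniformis,OM_area,413.3,18.5
Craticulina_tabaniformis,OM_number,1489.9,23.1
Craticulina_tabaniformis,delta_gamma,4.00,0.03
Craticulina_tabaniformis,OC_diameter,66.3,3.0
Eumacronychia_persolla,H_width,2153.3,64.3
Eumacronychia_persolla,E_area,426282.4,11766.2
Eumacronychia_persolla,OM_area,285.9,18.2
Eumacronychia_persolla,OM_number,1502.6,68.2
Eumacronychia_persolla,delta_gamma,3.99,0.09
Eumacronychia_persolla,OC_diameter,61.8,10.0
Metopia_argyrocephala,H_width,2012.0,34.4
Metopia_argyrocephala,E_area,441396.2,13343.4
Metopia_argyrocephala,OM_area,282.8,14.0
Metopia_argyrocephala,OM_number,1570.6,38.8
Metopia_argyrocephala,delta_gamma,3.90,0.05
Metopia_argyrocephala,OC_diameter,36.7,0.4
Miltogramma_germari,H_width,2559.0,62.6
Miltogramma_germari,E_area,827724.4,27060.3
Miltogramma_germari,OM_area,327.5,5.4
Miltogramma_germari,OM_number,2527.5,71.0
Miltogramma_germari,delta_gamma,3.07,0.04
Miltogramma_germari,OC_diameter,72.7,2.6
Miltogramma_punctata,H_width,2421.0,90.4
Miltogramma_punctata,E_area,936436.3,75090.6
Miltogramma_punctata,OM_area,356.0,27.8
Miltogramma_punctata,OM_number,2635.3,82.2
Miltogramma_punctata,delta_gamma,3.01,0.05
Miltogramma_punctata,OC_diameter,78.0,2.6
Miltogramma_turanica,H_width,2194.0,40.1
Miltogramma_turanica,E_area,893903.0,31581.7
Miltogramma_turanica,OM_area,345.6,8.0
Miltogramma_turanica,OM_number,2589.9,87.6
Miltogramma_turanica,delta_gamma,3.04,0.05
Miltogramma_turanica,OC_diameter,61.0,1.6
Phrosinella_fedtshenkoi,H_width,1984.6,35.2
Phrosinella_fedtshenkoi,E_area,397453.1,9953.1
Phrosinella_fedtshenkoi,OM_area,270.0,9.3
Phrosinella_fedtshenkoi,OM_number,1481.2,58.1
Phrosinella_fedtshenkoi,delta_gamma,4.02,0.08
Phrosinella_fedtshenkoi,OC_diameter,60.8,2.1
Phrosinella_kocaki,H_width,2049.0,62.1
Phrosinella_kocaki,E_area,417403.2,22927.2
Phrosinella_kocaki,OM_area,294.0,5.8
Phrosinella_kocaki,OM_number,1416.9,62.9
Phrosinella_kocaki,delta_gamma,4.12,0.09
Phrosinella_kocaki,OC_diameter,67.8,2.8
Phylloteles_pictipennis,H_width,1900.1,28.9
Phylloteles_pictipennis,E_area,381743.4,14846.8
Phylloteles_pictipennis,OM_area,276.6,6.1
Phylloteles_pictipennis,OM_number,1381.8,53.3
Phylloteles_pictipennis,delta_gamma,4.17,0.08
Phylloteles_pictipennis,OC_diameter,43.3,1.2
Pterella_melanura,H_width,1867.6,47.0
Pterella_melanura,E_area,536610.9,24617.6
Pterella_melanura,OM_area,241.7,8.4
Pterella_melanura,OM_number,2219.5,56.5
Pterella_melanura,delta_gamma,3.28,0.04
Pterella_melanura,OC_diameter,64.1,1.1
Senotainia_albifrons,H_width,2023.8,59.3
Senotainia_albifrons,E_area,584752.0,30448.3
Senotainia_albifrons,OM_area,332.0,13.9
Senotainia_albifrons,OM_number,1761.9,62.1
Senotainia_albifrons,delta_gamma,3.69,0.06
Senotainia_albifrons,OC_diameter,71.6,6.6
Senotainia_conica,H_width,1598.3,57.7
Senotainia_conica,E_area,383844.8,28873.1
Senotainia_conica,OM_area,252.7,12.7
Senotainia_conica,OM_number,1510.5,60.9
Senotainia_conica,delta_gamma,3.99,0.09
Senotainia_conica,OC_diameter,66.1,3.1
Senotainia_tricuspis,H_width,2464.8,47.6
Senotainia_tricuspis,E_area,642024.6,17713.1
Senotainia_tricuspis,OM_area,300.3,5.2
Senotainia_tricuspis,OM_number,2140.1,72.2
Senotainia_tricuspis,delta_gamma,3.34,0.06
Senotainia_tricuspis,OC_diameter,92.7,6.1
Sphenometopa_claripennis,H_width,2020.7,65.3
Sphenometopa_claripennis,E_area,457034.3,36559.1
Sphenometopa_claripennis,OM_area,299.1,9.5
Sphenometopa_claripennis,OM_number,1521.2,95.6
Sphenometopa_claripennis,delta_gamma,3.99,0.12
Sphenometopa_claripennis,OC_diameter,47.3,1.5
Taxigramma_heteroneura,H_width,1357.8,76.1
Taxigramma_heteroneura,E_area,252067.9,16010.4
Taxigramma_heteroneura,OM_area,224.7,7.8
Taxigramma_heteroneura,OM_number,1123.8,66.2
Taxigramma_heteroneura,delta_gamma,4.63,0.14
Taxigramma_heteroneura,OC_diameter,46.0,3.0
Taxigramma_stictica,H_width,1614.4,32.3
Taxigramma_stictica,E_area,306100.5,10115.5
Taxigramma_stictica,OM_area,239.1,7.4
Taxigramma_stictica,OM_number,1282.2,30.8
Taxigramma_stictica,delta_gamma,4.32,0.05
Taxigramma_stictica,OC_diameter,57.7,2.9
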