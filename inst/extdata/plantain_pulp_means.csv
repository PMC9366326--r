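# Mean metabolite concentrations (umol per g DW) in plantain pulp during
# development, cultivars Agbagba (AG) and Obino l'Ewai (OB), 2-12 weeks
# after bunch emergence. Starch expressed as glucose equivalents.
cultivar,week,metabolite,value,unit
AG,2,F6P,0.5,umol/gDW
AG,4,F6P,0.4,umol/gDW
AG,6,F6P,0.3,umol/gDW
AG,8,F6P,0.3,umol/gDW
AG,10,F6P,0.3,umol/gDW
AG,12,F6P,0.5,umol/gDW
OB,2,F6P,0.5,umol/gDW
OB,4,F6P,0.4,umol/gDW
OB,6,F6P,0.3,umol/gDW
OB,8,F6P,0.3,umol/gDW
OB,10,F6P,0.4,umol/gDW
OB,12,F6P,0.4,umol/gDW
AG,2,fructose,82.7,umol/gDW
AG,4,fructose,51.5,umol/gDW
AG,6,fructose,19.1,umol/gDW
AG,8,fructose,9.5,umol/gDW
AG,10,fructose,12.1,umol/gDW
AG,12,fructose,9.7,umol/gDW
OB,2,fructose,40.1,umol/gDW
OB,4,fructose,54.9,umol/gDW
OB,6,fructose,9.2,umol/gDW
OB,8,fructose,8.3,umol/gDW
OB,10,fructose,7.6,umol/gDW
OB,12,fructose,4.1,umol/gDW
AG,2,G1P,0.4,umol/gDW
AG,4,G1P,0.3,umol/gDW
AG,6,G1P,0.1,umol/gDW
AG,8,G1P,0.2,umol/gDW
AG,10,G1P,0.2,umol/gDW
AG,12,G1P,0.2,umol/gDW
OB,2,G1P,0.3,umol/gDW
OB,4,G1P,0.3,umol/gDW
OB,6,G1P,0.1,umol/gDW
OB,8,G1P,0.2,umol/gDW
OB,10,G1P,0.2,umol/gDW
OB,12,G1P,0.2,umol/gDW
AG,2,G6P,3.6,umol/gDW
AG,4,G6P,2.6,umol/gDW
AG,6,G6P,2.2,umol/gDW
AG,8,G6P,2.5,umol/gDW
AG,10,G6P,3.4,umol/gDW
AG,12,G6P,4.5,umol/gDW
OB,2,G6P,4.1,umol/gDW
OB,4,G6P,3.1,umol/gDW
OB,6,G6P,2.9,umol/gDW
OB,8,G6P,3.3,umol/gDW
OB,10,G6P,3.8,umol/gDW
OB,12,G6P,4.3,umol/gDW
AG,2,glucose,39.8,umol/gDW
AG,4,glucose,23.2,umol/gDW
AG,6,glucose,6.3,umol/gDW
AG,8,glucose,4.2,umol/gDW
AG,10,glucose,4.4,umol/gDW
AG,12,glucose,4.2,umol/gDW
OB,2,glucose,21.2,umol/gDW
OB,4,glucose,21.8,umol/gDW
OB,6,glucose,3.7,umol/gDW
OB,8,glucose,4.2,umol/gDW
OB,10,glucose,4.1,umol/gDW
OB,12,glucose,4.3,umol/gDW
AG,2,starch,266.2,umol/gDW
AG,4,starch,313.6,umol/gDW
AG,6,starch,386.6,umol/gDW
AG,8,starch,410.2,umol/gDW
AG,10,starch,457.4,umol/gDW
AG,12,starch,442.7,umol/gDW
OB,2,starch,268.3,umol/gDW
OB,4,starch,264.2,umol/gDW
OB,6,starch,305.8,umol/gDW
OB,8,starch,423.3,umol/gDW
OB,10,starch,449.1,umol/gDW
OB,12,starch,434,umol/gDW
AG,2,sucrose,92.1,umol/gDW
AG,4,sucrose,67.0,umol/gDW
AG,6,sucrose,75.5,umol/gDW
AG,8,sucrose,108.3,umol/gDW
AG,10,sucrose,127.8,umol/gDW
AG,12,sucrose,160.2,umol/gDW
OB,2,sucrose,98.8,umol/gDW
OB,4,sucrose,68.6,umol/gDW
OB,6,sucrose,108.3,umol/gDW
OB,8,sucrose,141.6,umol/gDW
OB,10,sucrose,156.1,umol/gDW
OB,12,sucrose,148.7,umol/gDW
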