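{"host":{"converged":true,"moved":true,"achieved":{"smin":0.199999930258334,"smax":0.299999709148484,"peak":12.0000067814162},"residuals":[-6.97416663308914e-08,-2.90851515538648e-07,6.78141615928496e-06],"target":{"smin":0.2,"smax":0.3,"peak":12},"loss":1.69298096345354e-13},"tumor_fast":{"converged":true,"moved":true,"achieved":{"smin":0.149999981614626,"smax":0.300000056908053,"peak":5.27139672972643},"residuals":[-1.83853740565176e-08,5.6908053214233e-08],"target":{"smin":0.15,"smax":0.3},"loss":3.57654849983204e-15},"tumor_slow":{"converged":true,"moved":true,"achieved":{"smin":0.420000146103024,"smax":0.469999844604133,"peak":18.1841321824966},"residuals":[1.46103024067923e-07,-1.55395866674457e-07],"target":{"smin":0.42,"smax":0.47},"loss":4.54939690212977e-14}}
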