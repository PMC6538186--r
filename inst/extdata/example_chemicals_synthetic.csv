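id,name,mw,logp,pka_donor,pka_acceptor,fup,fup_below_lod,clint_1,clint_10,logwsol,loghenry
EX-0001,examplol,312.4,2.8,,8.1,0.21,FALSE,12.5,9.8,-3.9,-8.2
EX-0002,examplinib,287.1,1.4,4.6,,0.66,FALSE,,3.2,-2.7,-9.5
EX-0003,examplate,401.9,4.2,,,,TRUE,0,,-5.1,-7.8
EX-0004,examplosin,176.2,0.6,9.2;4.1,,0.88,FALSE,1.1,2.0,-1.9,-10.3
EX-0005,examplamine,233.7,3.5,,9.7,0.04,FALSE,28.4,22.1,-4.4,-8.9
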