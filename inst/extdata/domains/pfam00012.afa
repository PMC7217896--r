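>pfam00012_seed1
CSQATRSRTYGFQEPTWFVYFSFRPQTVQVCKLFFGFFHVDRDCNMDSMEWHFLLRKCMQQRSGLGQAKMVTMQRWSHAL
>pfam00012_seed2
DSQAGRSNTYGFQLPTWFVYFSCRPQTVQVCELFFGFFHVDRDCNMDSTEWHFLLWKIMGQRSGLGQAKMVDMQQWSEAL
>pfam00012_seed3
CKQAGPSRTYGFQEPTWFVYFSFGPQFVQVCKLFFGFFHVDRDCNMDSLEWHFLLSKIMGQRSGLGQAKMVDMQQWSNAL
>pfam00012_seed4
FSQYGRSRTYGFQEPTWFKYFSFRPQTVQVCSLFFGFFHVDRDCNMYSTEWHFLLSKIMIQHAGLGQAKMVDMCQWSHAL
>pfam00012_seed5
CSQAGRSRTEISPWPTWFVHFSFRPQTVQCCKLFFGFFHVDRDCNDDSTEWEFLLMKIMGQRSGLGQAMMVMYQQWSHAL
>pfam00012_seed6
CSQFGRSRTYGFHEWTWFVYFTFQPQTVQVCKLFFGFFHVDRDCNMDCTEWHFLLVKIMGQRVGLGQAWMVDMQRWSHSL
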