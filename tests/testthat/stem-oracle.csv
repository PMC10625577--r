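word,stem
ability,abil
about,about
aca,aca
account,account
adjustable,adjust
adjustment,adjust
adoption,adopt
adult,adult
against,against
agreed,agre
airliner,airlin
allowance,allow
also,also
ambiguous,ambigu
among,among
andes,andes
any,ani
application,applic
applications,applic
applied,appli
approach,approach
arsenal,arsenal
assesses,assess
assign,assign
atlas,atlas
availability,avail
average,averag
background,background
baseline,baselin
before,befor
bias,bias
board,board
boosting,boost
both,both
bowdlerize,bowdler
branch,branch
bronchitis,bronchiti
builds,build
calculate,calcul
calculated,calcul
callousness,callous
canning,canning
carcinogens,carcinogen
case,case
category,categori
centers,center
challenge,challeng
character,charact
characteristics,characterist
cheaply,cheapli
circumstances,circumst
classifier,classifi
classify,classifi
clocacc,clocacc
codable,codabl
coders,coder
coding,code
coefficient,coeffici
coefficients,coeffici
columns,column
combination,combin
commission,commiss
committee,committe
communication,communic
competencies,compet
computation,comput
computed,comput
computer,comput
computing,comput
concerned,concern
conditional,condit
conflated,conflat
contain,contain
controller,control
converting,convert
correcting,correct
correctness,correct
cosmos,cosmos
could,could
cries,cri
custom,custom
data,data
death,death
decisiveness,decis
dedicated,dedic
defects,defect
defensible,defens
definitive,definit
denote,denot
dependent,depend
designed,design
deterministic,determinist
dies,die
digits,digit
disability,disabl
discussion,discuss
disp,disp
distribution,distribut
documentation,document
does,doe
dom,dom
due,due
dying,die
early,earli
earring,earring
effective,effect
effects,effect
efficient,effici
electricity,electr
embedders,embedd
empirically,empir
employer,employ
enable,enabl
ended,end
entirely,entir
environmental,environment
error,error
estimate,estim
estimates,estim
ethics,ethic
exceed,exceed
exceeding,exceed
excessively,excess
expected,expect
exposure,exposur
exppro,exppro
extended,extend
fact,fact
failing,fail
falseness,fals
feasible,feasibl
feature,featur
feudalism,feudal
filing,file
first,first
five,five
fixed,fix
fled,fled
food,food
form,form
formality,formal
formative,format
four,four
friesen,friesen
fully,fulli
furthermore,furthermor
gave,gave
gcmg,gcmg
generalization,general
generalized,general
generally,general
generously,generous
gently,gentl
given,given
goodness,good
gories,gori
graphs,graph
grid,grid
gyroscopic,gyroscop
hence,henc
here,here
herring,herring
histogram,histogram
homologous,homolog
hopeful,hope
hopefulness,hope
hoping,hope
hopping,hop
https,https
human,human
identify,identifi
idly,idl
imbalance,imbal
incomplete,incomplet
independently,independ
indicating,indic
individuals,individu
inference,infer
inning,inning
inserm,inserm
interval,interv
intervals,interv
interventions,intervent
investigators,investig
irritant,irrit
jem,jem
know,know
knowledge,knowledg
lack,lack
level,level
libert,libert
life,life
luxuriously,luxuri
lying,lie
major,major
manner,manner
marcel,marcel
matrices,matric
matrix,matrix
media,media
min,min
mobility,mobil
month,month
mother,mother
nathaniel,nathaniel
near,near
negatively,negat
netherlands,netherland
new,new
news,news
nickel,nickel
nine,nine
non,non
nonviable,nonviabl
noticed,notic
numbers,number
occupations,occup
occurring,occur
only,onli
operator,oper
optimal,optim
other,other
outcomes,outcom
outing,outing
outperforms,outperform
over,over
overfitting,overfit
pah,pah
paragraphs,paragraph
participants,particip
percentage,percentag
pesticides,pesticid
possibly,possibl
predication,predic
prediction,predict
present,present
prevent,prevent
prior,prior
pro,pro
probability,probabl
problems,problem
proceed,proceed
process,process
processed,process
produce,produc
professional,profession
professions,profess
radically,radic
range,rang
rater,rater
rationalization,ration
real,real
reducing,reduc
regression,regress
relatively,relat
remained,remain
replacement,replac
reported,report
respiratory,respiratori
retention,retent
reveal,reveal
revival,reviv
rey,rey
roll,roll
same,same
scale,scale
scenarios,scenario
secures,secur
selection,select
sensational,sensat
sensibility,sensibl
sentences,sentenc
separate,separ
seven,seven
showing,show
sided,side
signed,sign
since,sinc
sing,sing
singing,sing
single,singl
singly,singl
sites,site
six,six
sized,size
sizes,size
skating,skate
skies,sky
sky,sky
smote,smote
social,social
solvents,solvent
specific,specif
specify,specifi
statement,statement
statistics,statist
status,status
step,step
still,still
sub,sub
succeed,succeed
succeeding,succeed
suggested,suggest
supported,support
synthetic,synthet
system,system
take,take
takes,take
text,text
that,that
thereby,therebi
through,through
ties,tie
time,time
tno,tno
too,too
tooloccupational,tooloccup
tre,tre
trees,tree
triplicate,triplic
troubling,troubl
tuned,tune
ugly,ugli
underwent,underw
unit,unit
university,univers
usa,usa
usage,usag
used,use
values,valu
vapors,vapor
variances,varianc
vector,vector
vgdf,vgdf
vietnamization,vietnam
villejuif,villejuif
vjkv,vjkv
warranted,warrant
where,where
wide,wide
with,with
workers,worker
workload,workload
written,written
yield,yield
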